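#' Dynamic PET images
#'
#' A dynamic PET image couples a 4-D array of SUV values, ordered
#' `(time, depth, height, width)`, with the [frame_schedule()] it was
#' reconstructed into and the voxel spacing in millimetres.  The canonical
#' whole-body mouse geometry is 42 frames of 96 x 48 x 48 voxels.
#'
#' @param values 4-D numeric array `(time, depth, height, width)` of SUV
#'   (g/mL); all values finite.
#' @param schedule A [frame_schedule()] whose frame count equals
#'   `dim(values)[1]`.
#' @param spacing Numeric length-3 voxel spacing in mm `(depth, height,
#'   width)`.
#' @return A `dynamic_pet_image` object (list with `values`, `schedule`,
#'   `spacing`).
#' @export
dynamic_pet_image <- function(values, schedule, spacing = c(1, 1, 1)) {
  if (!is.array(values) || length(dim(values)) != 4L)
    stop("not a dynamic image: `values` must be a 4-D array (time, depth, height, width)")
  stopifnot(inherits(schedule, "frame_schedule"))
  if (dim(values)[1L] != nrow(schedule))
    stop("time dimension (", dim(values)[1L], ") does not match schedule (",
         nrow(schedule), " frames)")
  if (!all(is.finite(values))) stop("image values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive values (mm)")
  structure(list(values = values, schedule = schedule, spacing = spacing),
            class = "dynamic_pet_image")
}

#' @export
print.dynamic_pet_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dynamic_pet_image> %d frames x %d x %d x %d voxels, %.0f s total\n",
              d[1], d[2], d[3], d[4], schedule_end(x$schedule)))
  cat(sprintf("  spacing %.2f x %.2f x %.2f mm, SUV range [%.3g, %.3g]\n",
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @rdname dynamic_pet_image
#' @param image A `dynamic_pet_image`.
#' @export
n_frames <- function(image) {
  if (inherits(image, "dynamic_pet_image")) return(dim(image$values)[1L])
  if (inherits(image, "frame_schedule")) return(nrow(image))
  stop("`image` must be a dynamic_pet_image or frame_schedule")
}

#' Convert an activity-concentration image to standardized uptake values
#'
#' SUV = activity concentration x body weight / injected dose.  With
#' activity in kBq/mL, weight in g and dose in kBq the result carries units
#' of g/mL.
#'
#' @param activity Numeric array (any shape) of activity concentration in
#'   kBq/mL.
#' @param body_weight_g Body weight in grams (> 0).
#' @param injected_dose_kbq Injected dose in kBq (> 0).
#' @return Array of SUV values, same shape as `activity`.
#' @examples
#' suv_normalize(5, body_weight_g = 25, injected_dose_kbq = 8000)  # 0.015625
#' @export
suv_normalize <- function(activity, body_weight_g, injected_dose_kbq) {
  if (!is.numeric(body_weight_g) || length(body_weight_g) != 1L || body_weight_g <= 0)
    stop("`body_weight_g` must be a single positive number")
  if (!is.numeric(injected_dose_kbq) || length(injected_dose_kbq) != 1L ||
      injected_dose_kbq <= 0)
    stop("`injected_dose_kbq` must be a single positive number")
  activity * body_weight_g / injected_dose_kbq
}
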