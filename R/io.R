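#' Read and write dynamic PET images as NIfTI plus a timing sidecar
#'
#' The image is stored as a 4-D NIfTI volume with file dimensions
#' `(depth, height, width, time)` — the frame axis is the fourth NIfTI
#' dimension — and voxel spacing in the pixdim header.  Frame timing lives
#' in a CSV sidecar with columns `frame_index` (0-based), `start_s`,
#' `duration_s`; times are referenced to injection at t = 0.  Values are
#' written as float64 so round trips are lossless.
#'
#' @param image_path Path to a `.nii` / `.nii.gz` file.
#' @param timing_path Path to the timing sidecar CSV.
#' @return `read_dynamic_pet()` returns a [dynamic_pet_image()];
#'   `write_dynamic_pet()` returns `image_path` invisibly.
#' @export
read_dynamic_pet <- function(image_path, timing_path) {
  nii <- RNifti::readNifti(image_path)
  arr <- as.array(nii)
  if (length(dim(arr)) != 4L)
    stop("not a dynamic image: expected 4 dimensions, got ", length(dim(arr)))
  timing <- utils::read.csv(timing_path)
  need <- c("frame_index", "start_s", "duration_s")
  if (!all(need %in% names(timing)))
    stop("timing sidecar must have columns ", paste(need, collapse = ", "))
  if (nrow(timing) != dim(arr)[4L])
    stop("timing sidecar has ", nrow(timing), " rows for a ",
         dim(arr)[4L], "-frame image")
  timing <- timing[order(timing$frame_index), , drop = FALSE]
  sched <- frame_schedule(timing$start_s, timing$duration_s)
  pd <- attr(nii, "pixdim")
  spacing <- if (!is.null(pd) && length(pd) >= 3) as.numeric(pd[1:3]) else c(1, 1, 1)
  values <- aperm(arr, c(4L, 1L, 2L, 3L))
  dynamic_pet_image(values, sched, spacing)
}

#' @rdname read_dynamic_pet
#' @param image A [dynamic_pet_image()].
#' @export
write_dynamic_pet <- function(image, image_path, timing_path) {
  stopifnot(inherits(image, "dynamic_pet_image"))
  arr <- aperm(image$values, c(2L, 3L, 4L, 1L))
  nii <- RNifti::asNifti(arr, datatype = "double")
  attr(nii, "pixdim") <- c(image$spacing, 1)
  RNifti::writeNifti(nii, image_path, datatype = "double")
  sched <- image$schedule
  utils::write.csv(
    data.frame(frame_index = sched$frame - 1L,
               start_s = sched$start_s,
               duration_s = sched$duration_s),
    timing_path, row.names = FALSE)
  invisible(image_path)
}

#' Write an integer label volume (e.g. phantom organ masks) as NIfTI
#'
#' @param labels 3-D integer array `(depth, height, width)`.
#' @param path Output NIfTI path.
#' @param spacing Voxel spacing in mm.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(labels, path, spacing = c(1, 1, 1)) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  nii <- RNifti::asNifti(array(as.integer(labels), dim(labels)), datatype = "int16")
  attr(nii, "pixdim") <- as.numeric(spacing)
  RNifti::writeNifti(nii, path, datatype = "int16")
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3L) stop("expected a 3-D label volume")
  array(as.integer(round(arr)), dim(arr))
}
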