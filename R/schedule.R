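#' Frame schedules
#'
#' A frame schedule is the ordered list of acquisition-frame start times and
#' durations into which a dynamic PET scan is reconstructed.  It is stored as
#' a tibble with one row per frame and columns `frame` (1-based index),
#' `start_s`, `duration_s` and `midpoint_s`, all in seconds from injection at
#' t = 0.  Frames must be contiguous: each frame starts where the previous
#' one ends.
#'
#' @param starts Numeric vector of frame start times (seconds), strictly
#'   increasing, first frame at any non-negative time.
#' @param durations Numeric vector of frame durations (seconds), positive,
#'   same length as `starts`.
#' @return A `frame_schedule` tibble.
#' @examples
#' frame_schedule(c(0, 30, 35), c(30, 5, 5))
#' @export
frame_schedule <- function(starts, durations) {
  starts <- as.numeric(starts)
  durations <- as.numeric(durations)
  if (length(starts) != length(durations))
    stop("`starts` and `durations` must have the same length")
  if (length(starts) < 1L) stop("a schedule needs at least one frame")
  if (any(!is.finite(starts)) || any(!is.finite(durations)))
    stop("schedule times must be finite")
  if (any(durations <= 0)) stop("frame durations must be positive")
  if (starts[1L] < 0) stop("frame start times must be non-negative")
  if (length(starts) > 1L) {
    if (any(diff(starts) <= 0)) stop("frame start times must be strictly increasing")
    gap <- starts[-1L] - (starts[-length(starts)] + durations[-length(durations)])
    if (any(abs(gap) > 1e-9))
      stop("schedule is not contiguous: each frame must start where the previous ends")
  }
  out <- tibble::tibble(
    frame      = seq_along(starts),
    start_s    = starts,
    duration_s = durations,
    midpoint_s = starts + durations / 2
  )
  class(out) <- c("frame_schedule", class(out))
  out
}

#' Build a frame schedule from grouped frame counts and durations
#'
#' Dynamic protocols are usually quoted as groups, e.g. the canonical
#' small-animal scheme of 1 x 30 s, 24 x 5 s, 9 x 20 s and 8 x 300 s frames
#' (42 frames, 2730 s total).  This expands such a grouping into a contiguous
#' schedule starting at t = 0.
#'
#' @param group_counts Integer vector, number of frames in each group (>= 1).
#' @param group_durations Numeric vector, per-frame duration in seconds for
#'   each group (> 0); same length as `group_counts`.
#' @return A [frame_schedule()] tibble with `sum(group_counts)` frames.
#' @examples
#' sched <- build_schedule(c(1, 24, 9, 8), c(30, 5, 20, 300))
#' nrow(sched)            # 42
#' schedule_end(sched)    # 2730
#' @export
build_schedule <- function(group_counts, group_durations) {
  if (length(group_counts) != length(group_durations))
    stop("`group_counts` and `group_durations` must have the same length")
  if (any(group_counts < 1) || any(group_counts != round(group_counts)))
    stop("`group_counts` must be positive integers")
  if (any(group_durations <= 0)) stop("`group_durations` must be positive")
  durations <- rep(as.numeric(group_durations), times = as.integer(group_counts))
  starts <- cumsum(c(0, durations[-length(durations)]))
  frame_schedule(starts, durations)
}

#' The canonical 42-frame small-animal schedule
#'
#' 1 x 30 s, 24 x 5 s, 9 x 20 s, 8 x 300 s; 42 frames ending at 2730 s.
#'
#' @return A [frame_schedule()] tibble with 42 frames.
#' @export
canonical_schedule <- function() {
  build_schedule(c(1L, 24L, 9L, 8L), c(30, 5, 20, 300))
}

#' Recover the grouped representation of a schedule
#'
#' Inverse of [build_schedule()]: runs of equal frame duration are collapsed
#' back into `(count, duration)` groups.
#'
#' @param schedule A [frame_schedule()].
#' @return A list with elements `group_counts` and `group_durations`.
#' @export
regroup_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  r <- rle(schedule$duration_s)
  list(group_counts = r$lengths, group_durations = r$values)
}

#' @rdname build_schedule
#' @export
schedule_end <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  n <- nrow(schedule)
  schedule$start_s[n] + schedule$duration_s[n]
}

#' Re-anchor a schedule so that its first frame starts at t = 0
#'
#' Used after truncating a dynamic acquisition: the retained frames keep
#' their durations but times are referenced to the new scan start.
#'
#' @param schedule A [frame_schedule()].
#' @return A [frame_schedule()] starting at 0.
#' @export
reanchor_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  frame_schedule(schedule$start_s - schedule$start_s[1L], schedule$duration_s)
}

#' Subset contiguous frames of a schedule
#'
#' @param schedule A [frame_schedule()].
#' @param frames Integer vector of consecutive frame indices to keep.
#' @param reanchor Re-reference times to the new first frame (default TRUE).
#' @return A [frame_schedule()].
#' @export
subset_schedule <- function(schedule, frames, reanchor = TRUE) {
  stopifnot(inherits(schedule, "frame_schedule"))
  frames <- as.integer(frames)
  if (any(diff(frames) != 1L)) stop("`frames` must be consecutive")
  out <- frame_schedule(schedule$start_s[frames], schedule$duration_s[frames])
  if (reanchor) out <- reanchor_schedule(out)
  out
}
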