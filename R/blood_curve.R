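#' Blood activity curves
#'
#' A blood curve holds the tracer concentration in blood over time: either a
#' measured arterial input function (AIF), a network-predicted input function
#' (DLIF), or a plasma input function derived from whole blood.  It is a
#' tibble with columns `time_s` (seconds, strictly increasing; by convention
#' the frame midpoints of the acquisition schedule) and `suv` (standardized
#' uptake value, g/mL), with a `kind` attribute of `"whole_blood"` or
#' `"plasma"`.
#'
#' @param time_s Numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param suv Numeric vector of activity concentrations (SUV, g/mL).
#' @param kind `"whole_blood"` (default) or `"plasma"`.
#' @return A `blood_curve` tibble.
#' @export
blood_curve <- function(time_s, suv, kind = c("whole_blood", "plasma")) {
  kind <- match.arg(kind)
  time_s <- as.numeric(time_s)
  suv <- as.numeric(suv)
  if (length(time_s) != length(suv))
    stop("`time_s` and `suv` must have the same length")
  if (length(time_s) < 1L) stop("a blood curve needs at least one sample")
  if (any(!is.finite(time_s)) || any(!is.finite(suv)))
    stop("blood curve entries must be finite")
  if (length(time_s) > 1L && any(diff(time_s) <= 0))
    stop("blood curve times must be strictly increasing")
  out <- tibble::tibble(time_s = time_s, suv = suv)
  attr(out, "kind") <- kind
  class(out) <- c("blood_curve", class(out))
  out
}

#' @rdname blood_curve
#' @param curve A `blood_curve`.
#' @export
curve_kind <- function(curve) {
  stopifnot(inherits(curve, "blood_curve"))
  attr(curve, "kind")
}

#' Read / write a blood curve as CSV
#'
#' The on-disk format is a two-column CSV `time_s,suv` with a header row.
#' Round trips are lossless to full double precision.
#'
#' @param path Path to a CSV file.
#' @param kind Curve kind to attach on read (the CSV itself carries no kind).
#' @return `read_blood_curve()` returns a [blood_curve()];
#'   `write_blood_curve()` returns `path` invisibly.
#' @export
read_blood_curve <- function(path, kind = c("whole_blood", "plasma")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty blood-curve file: ", path)
  df <- utils::read.csv(path, colClasses = "numeric")
  if (nrow(df) == 0L) stop("empty blood-curve file: ", path)
  if (!all(c("time_s", "suv") %in% names(df)))
    stop("blood-curve CSV must have columns time_s, suv")
  if (anyDuplicated(df$time_s)) stop("duplicate time values in ", path)
  if (is.unsorted(df$time_s, strictly = TRUE)) stop("unsorted times in ", path)
  blood_curve(df$time_s, df$suv, kind = kind)
}

#' @rdname read_blood_curve
#' @param curve A [blood_curve()].
#' @export
write_blood_curve <- function(curve, path) {
  stopifnot(inherits(curve, "blood_curve"))
  df <- data.frame(time_s = curve$time_s, suv = curve$suv)
  # format() would truncate; write full precision explicitly
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s,suv", con)
  writeLines(paste(sprintf("%.17g", df$time_s), sprintf("%.17g", df$suv), sep = ","), con)
  invisible(path)
}
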