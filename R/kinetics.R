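#' Convert a whole-blood curve to a plasma input function
#'
#' Kinetic models are driven by the plasma concentration; whole-blood
#' measurements (and image-derived predictions) must be scaled by a
#' plasma-to-whole-blood ratio.  The ratio model is pluggable: a single
#' constant, or a data frame `(time_s, ratio)` interpolated linearly in
#' time (clamped at the ends).  The default ratio of 1 is a placeholder —
#' supply a tracer-specific model for real studies.
#'
#' @param curve A whole-blood [blood_curve()].
#' @param ratio A positive scalar, or a data frame with columns `time_s`
#'   and `ratio` (all ratios > 0).
#' @return A [blood_curve()] with `kind = "plasma"`.
#' @export
blood_to_plasma <- function(curve, ratio = 1) {
  stopifnot(inherits(curve, "blood_curve"))
  if (curve_kind(curve) != "whole_blood")
    stop("`curve` is already a plasma curve")
  if (is.data.frame(ratio)) {
    if (!all(c("time_s", "ratio") %in% names(ratio)))
      stop("ratio table needs columns time_s, ratio")
    if (any(ratio$ratio <= 0)) stop("ratios must be positive")
    r <- stats::approx(ratio$time_s, ratio$ratio, xout = curve$time_s, rule = 2)$y
  } else {
    if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0)
      stop("`ratio` must be a positive scalar or a (time_s, ratio) table")
    r <- rep(ratio, nrow(curve))
  }
  blood_curve(curve$time_s, curve$suv * r, kind = "plasma")
}

# Cumulative trapezoid integral of a curve anchored at (0, 0): tracer
# concentration is zero at injection.
cumint_from_zero <- function(time_s, values) {
  tt <- c(0, time_s); vv <- c(0, values)
  pracma::cumtrapz(tt, vv)[-1L]
}

# Shared core so voxelwise maps are bit-identical with single-curve fits.
patlak_core <- function(tissue_values, plasma_values, times, t_star) {
  use <- times >= t_star
  if (sum(use) < 2L) stop("fewer than 2 frames at or beyond t_star")
  if (any(plasma_values[use] <= 0)) stop("plasma concentration must be positive on used frames")
  integ <- cumint_from_zero(times, plasma_values)
  x <- (integ / plasma_values)[use]
  y <- (tissue_values / plasma_values)[use]
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  if (sxx == 0) stop("degenerate Patlak abscissa")
  slope <- sum((x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  fitted <- intercept + slope * x
  ss_res <- sum((y - fitted)^2); ss_tot <- sum((y - yb)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(slope_per_s = slope, intercept = intercept, r2 = r2,
       frames_used = sum(use), x = x, y = y)
}

#' Patlak graphical analysis of an irreversible tracer
#'
#' Ordinary least squares of the normalized tissue uptake
#' `y(T) = C_t(T)/C_p(T)` against the normalized integrated plasma input
#' `x(T) = int_0^T C_p dt / C_p(T)` over frames with midpoint `>= t_star`;
#' the integral is a trapezoid from injection with the curve anchored at
#' `(0, 0)`.  The slope is the net influx rate Ki, reported per minute; for
#' an irreversible 2TCM tissue it converges to `K1*k3/(k2+k3)` once the
#' linear phase is reached.
#'
#' @param tissue A [blood_curve()]-like tissue time-activity curve.
#' @param plasma A plasma [blood_curve()] on the same time grid, positive
#'   on all used frames.
#' @param t_star Start of the linear phase in seconds (default 600, the
#'   onset of the long late frames, past the distribution phase the Patlak
#'   model discards).
#' @return A `patlak_fit` object: `ki_per_min`, `intercept`, `r2`,
#'   `t_star`, `frames_used`, and a `data` tibble of the plot coordinates.
#' @export
patlak_fit <- function(tissue, plasma, t_star = 600) {
  stopifnot(inherits(tissue, "blood_curve"), inherits(plasma, "blood_curve"))
  if (nrow(tissue) != nrow(plasma) ||
      any(abs(tissue$time_s - plasma$time_s) > 1e-9))
    stop("tissue and plasma must share one time grid")
  core <- patlak_core(tissue$suv, plasma$suv, tissue$time_s, t_star)
  structure(list(ki_per_min = core$slope_per_s * 60,
                 intercept = core$intercept,
                 r2 = core$r2, t_star = t_star,
                 frames_used = core$frames_used,
                 data = tibble::tibble(x = core$x, y = core$y)),
            class = "patlak_fit")
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat(sprintf("<patlak_fit> Ki = %.5g /min, intercept = %.4g, r2 = %.4f (%d frames, t* = %g s)\n",
              x$ki_per_min, x$intercept, x$r2, x$frames_used, x$t_star))
  invisible(x)
}

#' Voxelwise Patlak net-influx mapping
#'
#' Applies [patlak_fit()] to the time-activity curve of every voxel in the
#' mask, with the identical arithmetic, so any masked voxel reproduces the
#' single-curve fit bit for bit.  Voxels where the fit fails (and all
#' unmasked voxels) are flagged `NA` rather than aborting the map.
#'
#' @param image A [dynamic_pet_image()].
#' @param plasma A plasma [blood_curve()] on the image's frame midpoints.
#' @param t_star Start of the linear phase (seconds).
#' @param mask Logical/0-1 array matching the spatial shape; `NULL` fits
#'   every voxel.
#' @return A list with 3-D arrays `ki` (per minute), `intercept`, `r2`,
#'   and `n_failed`.
#' @export
patlak_image <- function(image, plasma, t_star = 600, mask = NULL) {
  stopifnot(inherits(image, "dynamic_pet_image"), inherits(plasma, "blood_curve"))
  sp <- dim(image$values)[2:4]
  if (is.null(mask)) mask <- array(TRUE, sp)
  if (!all(dim(mask) == sp)) stop("mask shape must match the image spatial shape")
  mask <- array(as.logical(mask), sp)
  times <- image$schedule$midpoint_s
  if (nrow(plasma) != length(times) || any(abs(plasma$time_s - times) > 1e-9))
    stop("plasma curve must be sampled at the image frame midpoints")
  nf <- dim(image$values)[1L]
  flat <- matrix(image$values, nf, prod(sp))  # frames x voxels
  ki <- array(NA_real_, sp); intc <- array(NA_real_, sp); r2 <- array(NA_real_, sp)
  n_failed <- 0L
  for (ix in which(as.vector(mask))) {
    res <- tryCatch(patlak_core(flat[, ix], plasma$suv, times, t_star),
                    error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    ki[ix] <- res$slope_per_s * 60
    intc[ix] <- res$intercept
    r2[ix] <- res$r2
  }
  list(ki = ki, intercept = intc, r2 = r2, n_failed = n_failed)
}

# Fixed-grid forward model for the irreversible 2TCM with a piecewise
# linear plasma input: exponential-trapezoid recursion for C1 and
# trapezoidal accumulation for C2.  Unlike an adaptive ODE solver this is
# smooth in the rate constants, which the finite-difference Jacobian of
# the Levenberg-Marquardt fit requires; it agrees with simulate_2tcm() to
# the quadrature error of the grid step (O(h^2), below 1e-4 relative at
# the default h = 0.5 s).
tcm_forward_grid <- function(params, plasma_times, plasma_values, eval_times,
                             h = 0.5) {
  t_max <- max(eval_times)
  grid <- seq(0, t_max + h, by = h)
  cp <- stats::approx(c(0, plasma_times), c(0, plasma_values),
                      xout = grid, rule = 2)$y
  K1 <- params$K1 / 60; beta <- (params$k2 + params$k3) / 60
  k3 <- params$k3 / 60
  E <- exp(-beta * h)
  n <- length(grid)
  u <- K1 * h / 2 * (cp[-n] * E + cp[-1L])
  c1 <- c(0, as.numeric(stats::filter(u, E, method = "recursive")))
  c2 <- k3 * h * (cumsum(c1) - c1 / 2 - c1[1L] / 2)
  tissue <- (1 - params$vB) * (c1 + c2)
  out <- stats::approx(grid, tissue, xout = eval_times)$y
  if (params$vB > 0)
    out <- out + params$vB * stats::approx(c(0, plasma_times), c(0, plasma_values),
                                           xout = eval_times, rule = 2)$y
  out
}

#' Fit the irreversible two-tissue compartment model to a tissue curve
#'
#' Bounded weighted least squares (Levenberg-Marquardt via
#' [minpack.lm::nls.lm()]) of the irreversible 2TCM forward model,
#' evaluated at the curve's sample times with the plasma input
#' interpolated from its samples (anchored at zero at injection), against
#' the measured tissue curve.  The forward model is integrated on a fixed
#' fine grid so the objective is smooth in the rate constants; it matches
#' [simulate_2tcm()] to quadrature accuracy.  `k4` is fixed at 0.
#'
#' @param tissue A tissue [blood_curve()].
#' @param plasma A plasma [blood_curve()] on the same grid.
#' @param init A [kinetic_params()] starting point (must lie within the
#'   bounds).
#' @param lower,upper Named bounds for `K1`, `k2`, `k3`, `vB`
#'   (non-negative).
#' @param weights Residual weights (default uniform).
#' @param fit_vB Also fit the blood-volume fraction (default FALSE: fixed
#'   at `init$vB`).
#' @return A `tcm_fit` object: `params` ([kinetic_params()]), `ki_per_min`,
#'   `converged`, `residual_norm`, `n_iter`.
#' @export
fit_2tcm <- function(tissue, plasma, init = kinetic_params(),
                     lower = c(K1 = 0, k2 = 0, k3 = 0, vB = 0),
                     upper = c(K1 = 5, k2 = 5, k3 = 2, vB = 1),
                     weights = NULL, fit_vB = FALSE) {
  stopifnot(inherits(tissue, "blood_curve"), inherits(plasma, "blood_curve"),
            inherits(init, "kinetic_params"))
  if (nrow(tissue) != nrow(plasma) ||
      any(abs(tissue$time_s - plasma$time_s) > 1e-9))
    stop("tissue and plasma must share one time grid")
  if (any(lower < 0)) stop("bounds must be non-negative")
  nm <- if (fit_vB) c("K1", "k2", "k3", "vB") else c("K1", "k2", "k3")
  start <- unlist(init[nm])
  lo <- lower[nm]; hi <- upper[nm]
  if (any(start < lo) || any(start > hi))
    stop("`init` lies outside the bounds")
  if (is.null(weights)) weights <- rep(1, nrow(tissue))
  model <- function(par) {
    kp <- kinetic_params(K1 = par[["K1"]], k2 = par[["k2"]], k3 = par[["k3"]],
                         vB = if (fit_vB) par[["vB"]] else init$vB)
    tcm_forward_grid(kp, plasma$time_s, plasma$suv, tissue$time_s)
  }
  res <- minpack.lm::nls.lm(
    par = start, lower = lo, upper = hi,
    fn = function(par) sqrt(weights) * (model(par) - tissue$suv),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- res$par
  params <- kinetic_params(K1 = est[["K1"]], k2 = est[["k2"]], k3 = est[["k3"]],
                           vB = if (fit_vB) est[["vB"]] else init$vB)
  structure(list(params = params, ki_per_min = ki_macro(params),
                 converged = res$info %in% 1:4,
                 residual_norm = sqrt(sum(res$fvec^2)),
                 n_iter = res$niter),
            class = "tcm_fit")
}

#' @export
print.tcm_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("<tcm_fit> K1 = %.4g, k2 = %.4g, k3 = %.4g, vB = %.3g; Ki = %.5g /min (%s)\n",
              p$K1, p$k2, p$k3, p$vB, x$ki_per_min,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
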