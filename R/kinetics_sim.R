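#' Tissue kinetic parameters (irreversible two-tissue compartment model)
#'
#' Rate constants of the irreversible two-tissue compartment model (2TCM,
#' k4 = 0): `K1` (mL/cm^3/min) governs plasma-to-tissue transport, `k2`
#' (1/min) efflux back to plasma, `k3` (1/min) trapping into the second
#' compartment, and `vB` the fractional blood volume (0-1).  The macro
#' parameter net influx rate is `Ki = K1 * k3 / (k2 + k3)` (per minute).
#'
#' @param K1 Plasma-to-tissue rate, mL/cm^3/min (>= 0).
#' @param k2,k3 Tissue rate constants, 1/min (>= 0).
#' @param k4 Must be 0 (irreversible model only).
#' @param vB Fractional blood volume in the voxel, 0-1.
#' @return A `kinetic_params` object.
#' @export
kinetic_params <- function(K1 = 0.5, k2 = 0.3, k3 = 0.1, k4 = 0, vB = 0) {
  vals <- c(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vB = vB)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("kinetic parameters must be finite and non-negative")
  if (k4 != 0) stop("only the irreversible model (k4 = 0) is supported")
  if (vB > 1) stop("`vB` must lie in [0, 1]")
  structure(as.list(vals), class = "kinetic_params")
}

#' Net influx rate Ki of an irreversible 2TCM parameter set
#'
#' @param params A [kinetic_params()] object.
#' @return `K1 * k3 / (k2 + k3)` in mL/cm^3/min (0 when `k2 + k3 = 0`).
#' @export
ki_macro <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$k2 + params$k3 == 0) return(0)
  params$K1 * params$k3 / (params$k2 + params$k3)
}

#' Simulate an irreversible 2TCM tissue time-activity curve
#'
#' Integrates the compartment system
#' \deqn{dC_1/dt = K_1 C_p(t) - (k_2 + k_3) C_1, \qquad dC_2/dt = k_3 C_1}
#' (rates per minute, time in seconds internally converted) and returns the
#' measurable tissue concentration
#' `(1 - vB) * (C1 + C2) + vB * Cwb(t)` on `t_grid`.
#'
#' @param params A [kinetic_params()] with `k4 = 0`.
#' @param plasma_fn Function of time (seconds) giving the plasma input
#'   concentration (SUV).
#' @param t_grid Increasing numeric vector of evaluation times in seconds.
#' @param whole_blood_fn Function for the whole-blood concentration used for
#'   the vascular fraction; defaults to `plasma_fn`.
#' @param rtol,atol Solver tolerances passed to [deSolve::ode()].
#' @return Numeric vector of tissue SUV values on `t_grid`.
#' @export
simulate_2tcm <- function(params, plasma_fn, t_grid,
                          whole_blood_fn = plasma_fn,
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "kinetic_params"))
  t_grid <- as.numeric(t_grid)
  if (length(t_grid) < 1L || (length(t_grid) > 1L && any(diff(t_grid) <= 0)))
    stop("`t_grid` must be increasing")
  # rates are per minute; integrate in seconds
  K1 <- params$K1 / 60; k2 <- params$k2 / 60; k3 <- params$k3 / 60
  times <- unique(sort(c(0, t_grid)))
  deriv <- function(t, y, parms) {
    cp <- plasma_fn(t)
    list(c(K1 * cp - (k2 + k3) * y[1], k3 * y[1]))
  }
  sol <- deSolve::ode(y = c(C1 = 0, C2 = 0), times = times, func = deriv,
                      parms = NULL, rtol = rtol, atol = atol)
  idx <- match(t_grid, times)
  c1 <- sol[idx, "C1"]; c2 <- sol[idx, "C2"]
  (1 - params$vB) * (c1 + c2) + params$vB * whole_blood_fn(t_grid)
}

#' Average a continuous concentration curve over acquisition frames
#'
#' Each frame value is the mean of the curve over the frame interval,
#' `(1/dur) * integral(f, start, end)`, evaluated by adaptive quadrature
#' ([stats::integrate()], relative tolerance 1e-8, with a 401-point Simpson
#' fallback for non-smooth integrands).  The returned curve is sampled at
#' the frame midpoints.
#'
#' @param f Function of time (seconds) defined on `[0, schedule end]`.
#' @param schedule A [frame_schedule()].
#' @param kind Curve kind for the result.
#' @return A [blood_curve()] with one value per frame.
#' @export
frame_average <- function(f, schedule, kind = "whole_blood") {
  stopifnot(inherits(schedule, "frame_schedule"))
  vals <- vapply(seq_len(nrow(schedule)), function(i) {
    a <- schedule$start_s[i]
    b <- a + schedule$duration_s[i]
    v <- tryCatch(
      stats::integrate(f, a, b, rel.tol = 1e-8, subdivisions = 200L)$value,
      error = function(e) {
        x <- seq(a, b, length.out = 401L)
        y <- f(x)
        h <- (b - a) / 400
        h / 3 * (y[1] + y[401] + 4 * sum(y[seq(2, 400, 2)]) + 2 * sum(y[seq(3, 399, 2)]))
      })
    v / (b - a)
  }, numeric(1))
  blood_curve(schedule$midpoint_s, vals, kind = kind)
}
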