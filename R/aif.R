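#' Parametric arterial input function (tri-exponential bolus model)
#'
#' Ground-truth input functions for the synthetic phantoms follow the
#' classic tri-exponential bolus form used for FDG input functions
#' (Feng-type): zero before the arrival delay `t0`, then
#' \deqn{C(t) = (A_1\tau - A_2 - A_3)e^{-\lambda_1\tau} + A_2 e^{-\lambda_2\tau}
#'   + A_3 e^{-\lambda_3\tau}, \quad \tau = t - t_0,}
#' which rises linearly out of zero at `t0`, peaks within the bolus phase
#' and decays to a slow washout tail.  Continuity at `t0` holds by
#' construction (`C(t0) = 0`).
#'
#' @param A1 Bolus amplitude slope, SUV/s.
#' @param A2,A3 Exponential amplitudes, SUV (>= 0).
#' @param lambda1,lambda2,lambda3 Decay rates, 1/s; must satisfy
#'   `lambda1 > lambda2 > lambda3 > 0`.
#' @param t0 Tracer arrival delay in seconds (>= 0).
#' @return An `aif_params` object.
#' @export
aif_params <- function(A1 = 2.5, A2 = 0.7, A3 = 0.5,
                       lambda1 = 0.09, lambda2 = 0.012, lambda3 = 0.00017,
                       t0 = 5) {
  vals <- c(A1 = A1, A2 = A2, A3 = A3,
            lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3, t0 = t0)
  if (any(!is.finite(vals))) stop("AIF parameters must be finite")
  if (!(lambda1 > lambda2 && lambda2 > lambda3 && lambda3 > 0))
    stop("decay rates must satisfy lambda1 > lambda2 > lambda3 > 0")
  if (A2 < 0 || A3 < 0) stop("A2 and A3 must be non-negative")
  if (t0 < 0) stop("t0 must be non-negative")
  structure(as.list(vals), class = "aif_params")
}

#' Evaluate the tri-exponential input-function model
#'
#' @param params An [aif_params()] object.
#' @param t Numeric vector of times in seconds (>= 0).
#' @return Numeric vector of SUV values, zero for `t < t0`.
#' @examples
#' p <- aif_params()
#' aif_model(p, p$t0)   # 0 by construction
#' @export
aif_model <- function(params, t) {
  stopifnot(inherits(params, "aif_params"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("`t` must be non-negative")
  tau <- t - params$t0
  out <- numeric(length(t))
  on <- tau >= 0
  tp <- tau[on]
  out[on] <- (params$A1 * tp - params$A2 - params$A3) * exp(-params$lambda1 * tp) +
    params$A2 * exp(-params$lambda2 * tp) +
    params$A3 * exp(-params$lambda3 * tp)
  out
}

#' Turn an aif_params object into a plain function of time
#'
#' @param params An [aif_params()] object.
#' @return A function `f(t)` returning SUV.
#' @export
aif_function <- function(params) {
  force(params)
  function(t) aif_model(params, t)
}
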