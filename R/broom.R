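#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.patlak_fit <- function(x, ...) {
  tibble::tibble(term = c("Ki", "intercept"),
                 estimate = c(x$ki_per_min, x$intercept),
                 unit = c("1/min", "unitless"))
}

#' @export
glance.patlak_fit <- function(x, ...) {
  tibble::tibble(ki_per_min = x$ki_per_min, intercept = x$intercept,
                 r.squared = x$r2, t_star_s = x$t_star,
                 frames_used = x$frames_used)
}

#' @export
tidy.tcm_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(term = c("K1", "k2", "k3", "vB"),
                 estimate = c(p$K1, p$k2, p$k3, p$vB),
                 unit = c("mL/cm^3/min", "1/min", "1/min", "unitless"))
}

#' @export
glance.tcm_fit <- function(x, ...) {
  tibble::tibble(ki_per_min = x$ki_per_min, converged = x$converged,
                 residual_norm = x$residual_norm, n_iter = x$n_iter)
}

#' @export
tidy.curve_comparison <- function(x, ...) x$diffs

#' @export
glance.curve_comparison <- function(x, ...) {
  tibble::tibble(mse = x$mse, r = x$r, r.squared = x$r2,
                 deming_slope = x$deming_slope,
                 deming_intercept = x$deming_intercept,
                 t_statistic = x$t_statistic, p.value = x$p_value,
                 significant = x$significant)
}

#' @export
glance.fcdlif_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history),
                 first_loss = x$history$loss[1L],
                 final_loss = x$history$loss[nrow(x$history)],
                 n_parameters = count_parameters(x$network))
}
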