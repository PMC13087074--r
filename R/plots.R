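#' Plot a blood curve
#'
#' @param object A [blood_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.blood_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s / 60, y = .data$suv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (min)", y = "SUV (g/mL)",
                  title = paste0("blood curve (", attr(object, "kind"), ")")) +
    ggplot2::theme_minimal()
}

#' Plot a prediction against its measured curve
#'
#' Left to the reader on a single panel: measured and predicted curves over
#' time, coloured by temporal segment.
#'
#' @param object A `curve_comparison` from [compare_curves()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.curve_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(object$diffs, c("predicted", "measured"),
                            names_to = "curve", values_to = "suv")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s / 60, y = .data$suv,
                                   linetype = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "SUV (g/mL)",
                  subtitle = sprintf("MSE %.4g, r = %.3f", object$mse, object$r)) +
    ggplot2::theme_minimal()
}

#' Patlak plot
#'
#' @param object A `patlak_fit`.
#' @param ... Unused.
#' @return A ggplot of the linearized coordinates with the fitted line.
#' @export
autoplot.patlak_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$ki_per_min / 60,
                         intercept = object$intercept, linetype = 2) +
    ggplot2::labs(x = "normalized integrated plasma (s)",
                  y = "normalized tissue uptake",
                  subtitle = sprintf("Ki = %.4g /min, r2 = %.3f",
                                     object$ki_per_min, object$r2)) +
    ggplot2::theme_minimal()
}

#' Training loss history
#'
#' @param object An `fcdlif_fit` from [train_network()].
#' @param ... Unused.
#' @return A ggplot of the per-epoch weighted MSE.
#' @export
autoplot.fcdlif_fit <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "weighted MSE") +
    ggplot2::theme_minimal()
}

#' Plot a t-SNE embedding of frame features
#'
#' @param embedding Tibble from [tsne_features()].
#' @param colour `"segment"` or `"group"`.
#' @return A ggplot.
#' @export
plot_embedding <- function(embedding, colour = c("segment", "group")) {
  colour <- match.arg(colour)
  ggplot2::ggplot(embedding,
                  ggplot2::aes(x = .data$dim1, y = .data$dim2,
                               colour = .data[[colour]])) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
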