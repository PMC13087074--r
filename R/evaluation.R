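#' Compare a predicted input function with a measured one
#'
#' Frame-by-frame comparison of two curves on the same time grid:
#' unweighted MSE, per-frame paired differences with segment labels,
#' Pearson correlation (flagged `NA` when either curve is constant),
#' coefficient of determination (the squared Pearson correlation, which
#' equals the squared correlation between the measured values and the
#' fitted values of any straight line, orthogonal or ordinary), the
#' orthogonal (Deming, variance ratio 1) regression line, a paired t-test
#' across frames at `alpha = 0.05`, and sorted quantile-quantile pairs for
#' normality inspection.
#'
#' @param predicted,measured [blood_curve()]s on identical time grids.
#' @param alpha Significance level for the paired t-test.
#' @return A `curve_comparison` object.
#' @export
compare_curves <- function(predicted, measured, alpha = 0.05) {
  stopifnot(inherits(predicted, "blood_curve"), inherits(measured, "blood_curve"))
  if (nrow(predicted) != nrow(measured) ||
      any(abs(predicted$time_s - measured$time_s) > 1e-9))
    stop("curves must share one time grid")
  py <- predicted$suv; my <- measured$suv
  n <- length(py)
  times <- measured$time_s
  diffs <- tibble::tibble(
    time_s = times,
    predicted = py, measured = my,
    diff = py - my,
    segment = segment_labels(times))
  mse <- mean((py - my)^2)
  const <- stats::sd(py) == 0 || stats::sd(my) == 0
  r <- if (const) NA_real_ else stats::cor(py, my)
  dem <- if (const) list(slope = NA_real_, intercept = NA_real_)
         else deming_regression(my, py)
  tt <- if (n >= 2 && stats::sd(py - my) > 0)
    stats::t.test(py, my, paired = TRUE) else NULL
  structure(list(
    mse = mse,
    r = r,
    r2 = if (is.na(r)) NA_real_ else r^2,
    deming_slope = dem$slope,
    deming_intercept = dem$intercept,
    t_statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
    p_value = if (is.null(tt)) NA_real_ else tt$p.value,
    significant = if (is.null(tt)) NA else tt$p.value < alpha,
    alpha = alpha,
    diffs = diffs,
    qq = tibble::tibble(predicted_q = sort(py), measured_q = sort(my))),
    class = "curve_comparison")
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat(sprintf("<curve_comparison> MSE %.5g, r %.4f, r2 %.4f, Deming slope %.4f / intercept %.4g\n",
              x$mse, x$r, x$r2, x$deming_slope, x$deming_intercept))
  cat(sprintf("  paired t across frames: t = %.3f, p = %.3g%s\n",
              x$t_statistic, x$p_value,
              if (isTRUE(x$significant)) " (significant)" else ""))
  invisible(x)
}

#' Per-frame paired t-tests across a dataset
#'
#' For every time frame, a paired t-test of predicted against measured
#' values across samples.  P-values are reported unadjusted by default;
#' Bonferroni correction over frames is available.
#'
#' @param predicted,measured Lists of [blood_curve()]s (one per sample, all
#'   on the same grid).
#' @param p_adjust `"none"` (default) or `"bonferroni"`.
#' @param alpha Significance level.
#' @return A tibble with columns `frame`, `time_s`, `mean_diff`,
#'   `t_statistic`, `p_value`, `significant`.
#' @export
frame_ttests <- function(predicted, measured, p_adjust = c("none", "bonferroni"),
                         alpha = 0.05) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(length(predicted) == length(measured), length(predicted) >= 2L)
  P <- vapply(predicted, function(b) b$suv, numeric(nrow(predicted[[1L]])))
  M <- vapply(measured, function(b) b$suv, numeric(nrow(measured[[1L]])))
  times <- predicted[[1L]]$time_s
  res <- lapply(seq_len(nrow(P)), function(i) {
    d <- P[i, ] - M[i, ]
    if (stats::sd(d) == 0) return(c(mean(d), NA_real_, NA_real_))
    tt <- stats::t.test(P[i, ], M[i, ], paired = TRUE)
    c(mean(d), unname(tt$statistic), tt$p.value)
  })
  res <- do.call(rbind, res)
  pv <- stats::p.adjust(res[, 3L], method = p_adjust)
  tibble::tibble(frame = seq_len(nrow(P)), time_s = times,
                 mean_diff = res[, 1L], t_statistic = res[, 2L],
                 p_value = pv, significant = !is.na(pv) & pv < alpha)
}

#' Orthogonal (Deming) regression
#'
#' Errors-in-variables straight line minimizing the variance-weighted
#' perpendicular distances, appropriate when both coordinates carry
#' measurement error.  `variance_ratio` is the ratio of the error variance
#' in `y` to that in `x`; the default 1 gives the fully orthogonal fit, and
#' the limit `variance_ratio -> Inf` recovers ordinary least squares of `y`
#' on `x`.  With ratio 1 the fit is symmetric: swapping `x` and `y`
#' reciprocates the slope.
#'
#' @param x,y Numeric vectors (>= 2 points, not all identical).
#' @param variance_ratio Positive ratio of y-error variance to x-error
#'   variance.
#' @return List with `slope` and `intercept`.
#' @export
deming_regression <- function(x, y, variance_ratio = 1) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 2L)
    stop("need at least two (x, y) points")
  if (variance_ratio <= 0) stop("`variance_ratio` must be positive")
  sxx <- sum((x - mean(x))^2); syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  if (sxx == 0 && syy == 0) stop("all points identical")
  d <- variance_ratio
  if (sxy == 0) {
    # axis-aligned degenerate cases
    slope <- if (syy >= d * sxx) Inf else 0
    if (!is.finite(slope)) stop("vertical line: slope undefined")
  } else {
    slope <- (syy - d * sxx + sqrt((syy - d * sxx)^2 + 4 * d * sxy^2)) / (2 * sxy)
  }
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Rank curve comparisons by unweighted MSE
#'
#' @param comparisons Non-empty list of [compare_curves()] results (or a
#'   numeric vector of MSEs).
#' @return List with integer `best`, `median`, `worst` indices into the
#'   input (ascending MSE; the median is element `floor(n/2) + 1` of the
#'   sorted order; ties broken by lower index).
#' @export
rank_samples <- function(comparisons) {
  if (length(comparisons) == 0L) stop("`comparisons` must not be empty")
  mses <- if (is.numeric(comparisons)) comparisons
          else vapply(comparisons, function(cmp) cmp$mse, numeric(1))
  ord <- order(mses, seq_along(mses))
  n <- length(mses)
  list(best = ord[1L], median = ord[n %/% 2L + 1L],
       worst = which.max(mses))  # ties broken by the lower index
}

#' Time-shift an image by prepending one 30-second frame
#'
#' Simulates a delayed tracer injection: a 30 s frame is inserted before
#' the scan start (`mode = "empty"`: all-zero frame; `mode = "copy"`:
#' duplicate of the first frame) and the schedule is extended accordingly.
#'
#' @param image A [dynamic_pet_image()].
#' @param mode `"empty"` or `"copy"`.
#' @param frame_duration_s Duration of the inserted frame.
#' @return A [dynamic_pet_image()] with `T + 1` frames.
#' @export
shift_image <- function(image, mode = c("empty", "copy"), frame_duration_s = 30) {
  mode <- match.arg(mode)
  stopifnot(inherits(image, "dynamic_pet_image"))
  d <- dim(image$values)
  new_frame <- if (mode == "empty") array(0, c(1L, d[2:4]))
               else image$values[1L, , , , drop = FALSE]
  values <- array(0, c(d[1L] + 1L, d[2:4]))
  values[1L, , , ] <- new_frame
  values[-1L, , , ] <- image$values
  sched <- image$schedule
  new_sched <- frame_schedule(c(0, sched$start_s + frame_duration_s),
                              c(frame_duration_s, sched$duration_s))
  dynamic_pet_image(values, new_sched, image$spacing)
}

#' Truncate an image at both ends of the time series
#'
#' Removes the first `drop_head` and last `drop_tail` frames (defaults 4
#' and 6: on the canonical schedule the first ~40 s and the last 30 min)
#' and re-anchors the schedule to the new scan start, simulating a shorter
#' protocol with injection at scan start.
#'
#' @param image A [dynamic_pet_image()].
#' @param drop_head,drop_tail Number of frames removed at each end.
#' @return A [dynamic_pet_image()] with `T - drop_head - drop_tail` frames.
#' @export
truncate_image <- function(image, drop_head = 4L, drop_tail = 6L) {
  stopifnot(inherits(image, "dynamic_pet_image"))
  nf <- n_frames(image)
  keep <- seq.int(drop_head + 1L, nf - drop_tail)
  if (length(keep) < 1L) stop("too few frames to truncate")
  values <- image$values[keep, , , , drop = FALSE]
  dynamic_pet_image(values, subset_schedule(image$schedule, keep),
                    image$spacing)
}

#' Time-shift robustness test
#'
#' Predicts the input function for an image and for the same image with one
#' 30 s frame prepended, and scores the alignment: the MSE between the
#' original prediction and the shifted prediction with its first frame
#' dropped.  A temporally covariant network yields a near-zero score away
#' from the TFE receptive-field boundary.
#'
#' @param network An `fcdlif_network`.
#' @param image A [dynamic_pet_image()].
#' @param mode Frame content for the insertion, see [shift_image()].
#' @return List with `original` and `shifted` [blood_curve()]s and the
#'   `alignment_score`.
#' @export
shift_test <- function(network, image, mode = c("empty", "copy")) {
  mode <- match.arg(mode)
  original <- predict_aif(network, image)
  shifted_img <- shift_image(image, mode)
  shifted <- predict_aif(network, shifted_img)
  alignment <- mean((original$suv - shifted$suv[-1L])^2)
  list(original = original, shifted = shifted, alignment_score = alignment)
}

#' Truncation robustness test
#'
#' Predicts the input function after removing the first 4 and last 6
#' frames, returning the truncated-input prediction alongside the retained
#' frame indices of the source image.
#'
#' @inheritParams shift_test
#' @param drop_head,drop_tail Frames removed at each end.
#' @return List with `truncated` ([blood_curve()] on the re-anchored
#'   schedule) and `retained_frames`.
#' @export
truncate_test <- function(network, image, drop_head = 4L, drop_tail = 6L) {
  stopifnot(inherits(image, "dynamic_pet_image"))
  if (n_frames(image) < drop_head + drop_tail + 1L)
    stop("image has too few frames")
  trunc <- truncate_image(image, drop_head, drop_tail)
  list(truncated = predict_aif(network, trunc),
       retained_frames = seq.int(drop_head + 1L, n_frames(image) - drop_tail))
}

#' t-SNE embedding of per-frame spatial features
#'
#' Embeds the SFE feature vectors of one or more scans into 2-D with exact
#' (dense) t-SNE, labelling every point with its temporal segment
#' (peak / intermediate / tail) and its source group.  Deterministic for a
#' fixed seed.
#'
#' @param features A `(N x feature_dim)` matrix, or a named list of
#'   `(T x feature_dim)` matrices from [extract_features()] (names become
#'   group labels).
#' @param times Frame midpoint times for segment labelling: a vector
#'   (recycled per matrix) or `NULL` to label by canonical position.
#' @param groups Optional explicit group label per row.
#' @param seed Integer seed.
#' @param perplexity t-SNE perplexity (effective neighbourhood size).
#' @param n_iter Gradient-descent iterations.
#' @return A tibble with columns `dim1`, `dim2`, `segment`, `group`.
#' @export
tsne_features <- function(features, times = NULL, groups = NULL, seed = 1L,
                          perplexity = 15, n_iter = 500L) {
  if (is.list(features) && !is.matrix(features)) {
    groups <- rep(if (!is.null(names(features))) names(features)
                  else as.character(seq_along(features)),
                  vapply(features, nrow, integer(1)))
    if (!is.null(times)) times <- rep(times, length.out = sum(vapply(features, nrow, integer(1))))
    features <- do.call(rbind, features)
  }
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 5L) stop("need at least 5 feature rows")
  if (is.null(groups)) groups <- rep("all", n)
  seg <- if (is.null(times)) factor(rep("peak", n), levels = c("peak", "intermediate", "tail"))
         else segment_labels(times)
  emb <- tsne_exact(features, seed = seed, perplexity = perplexity, n_iter = n_iter)
  tibble::tibble(dim1 = emb[, 1L], dim2 = emb[, 2L], segment = seg,
                 group = groups)
}

# Exact t-SNE (dense pairwise affinities, gradient descent with momentum
# and early exaggeration).  Adequate for the few hundred frame vectors a
# study produces; O(N^2) memory and time.
tsne_exact <- function(X, seed = 1L, perplexity = 15, n_iter = 500L,
                       eta = 100, momentum = c(0.5, 0.8), exaggeration = 4) {
  n <- nrow(X)
  perplexity <- min(perplexity, (n - 1) / 3)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sump <- sum(p)
      if (sump == 0) { H <- 0; p[] <- 0 }
      else {
        H <- log(sump) + beta * sum(di * p) / sump
        p <- p / sump
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { betamin <- beta; beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2 }
      else { betamax <- beta; beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P[P < .Machine$double.eps] <- .Machine$double.eps
  Y <- withr::with_seed(as.integer(seed),
                        matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  dY <- matrix(0, n, 2)
  Pex <- P * exaggeration
  for (it in seq_len(n_iter)) {
    Puse <- if (it <= 100) Pex else P
    mom <- if (it <= 250) momentum[1] else momentum[2]
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < .Machine$double.eps] <- .Machine$double.eps
    W <- (Puse - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    dY <- mom * dY - eta * grad
    Y <- dY + Y
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
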