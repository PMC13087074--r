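#' Segment-weighted mean squared error
#'
#' The training loss divides the canonical 42-frame curve into peak
#' (first 25 frames), intermediate (middle 9) and tail (last 8) segments
#' with weights 0.4, 0.7 and 1.0 — roughly inversely proportional to the
#' sampling density, so the densely sampled early bolus phase does not
#' dominate.  The loss is the weight-multiplied squared error averaged over
#' frames: `(1/T) * sum_t w_t (pred_t - target_t)^2`.
#'
#' @param segment_counts Frames per segment on the canonical schedule.
#' @param segment_weights Positive weight per segment.
#' @return A `loss_weights` object.
#' @export
loss_weights <- function(segment_counts = c(25L, 9L, 8L),
                         segment_weights = c(0.4, 0.7, 1.0)) {
  if (length(segment_counts) != length(segment_weights))
    stop("counts and weights must have the same length")
  if (any(segment_weights <= 0)) stop("segment weights must be positive")
  if (any(segment_counts < 1)) stop("segment counts must be positive")
  structure(list(segment_counts = as.integer(segment_counts),
                 segment_weights = as.numeric(segment_weights)),
            class = "loss_weights")
}

# Segment boundaries in time, taken from the canonical split: the 25th
# frame ends at 150 s and the 34th at 330 s.  Used to label frames of
# non-canonical schedules.
segment_time_breaks <- c(peak_end = 150, intermediate_end = 330)

#' Label frames as peak / intermediate / tail
#'
#' On a 42-frame curve the canonical 25/9/8 count split is used; for any
#' other length, frames are assigned by their midpoint time against the
#' canonical split's boundaries in time (peak < 150 s <= intermediate
#' < 330 s <= tail).
#'
#' @param times Frame midpoint times in seconds.
#' @param weights A [loss_weights()].
#' @return Factor vector with levels peak, intermediate, tail.
#' @export
segment_labels <- function(times, weights = loss_weights()) {
  n <- length(times)
  lv <- c("peak", "intermediate", "tail")
  if (n == sum(weights$segment_counts)) {
    lab <- rep(lv, times = weights$segment_counts)
  } else {
    lab <- ifelse(times < segment_time_breaks[["peak_end"]], "peak",
                  ifelse(times < segment_time_breaks[["intermediate_end"]],
                         "intermediate", "tail"))
  }
  factor(lab, levels = lv)
}

expand_loss_weights <- function(weights, times) {
  stopifnot(inherits(weights, "loss_weights"))
  w <- weights$segment_weights[as.integer(segment_labels(times, weights))]
  as.numeric(w)
}

#' @rdname loss_weights
#' @param predicted,target [blood_curve()]s (or plain numeric vectors) of
#'   equal length.
#' @param weights A [loss_weights()]; pass `NULL` for the unweighted MSE.
#' @return `weighted_mse()` returns a non-negative scalar, zero iff the
#'   curves are identical.
#' @examples
#' t42 <- canonical_schedule()$midpoint_s
#' a <- blood_curve(t42, rep(1, 42)); b <- blood_curve(t42, rep(2, 42))
#' weighted_mse(a, b)  # (25*0.4 + 9*0.7 + 8*1)/42 = 0.578...
#' @export
weighted_mse <- function(predicted, target, weights = loss_weights()) {
  py <- if (inherits(predicted, "blood_curve")) predicted$suv else as.numeric(predicted)
  ty <- if (inherits(target, "blood_curve")) target$suv else as.numeric(target)
  if (length(py) != length(ty))
    stop("curve length mismatch: ", length(py), " vs ", length(ty))
  times <- if (inherits(target, "blood_curve")) target$time_s
           else if (inherits(predicted, "blood_curve")) predicted$time_s
           else seq_along(ty)
  w <- if (is.null(weights)) rep(1, length(ty)) else expand_loss_weights(weights, times)
  mean(w * (py - ty)^2)
}

#' Poisson count-noise augmentation
#'
#' Draws one noise scale `p ~ Unif(0, 1)` per image, then adds zero-mean
#' Poisson perturbations voxelwise: with rate `lambda = I * p` (negative
#' intensities clamped to zero for the rate), the augmented intensity is
#' `I + Pois(lambda) - lambda`.  The expectation equals the input
#' voxelwise, zero voxels pass through exactly, and `p -> 0` recovers the
#' identity.  Uses the current R RNG stream (seed at the call site for
#' reproducibility).
#'
#' @param image A [dynamic_pet_image()].
#' @param p Optional fixed noise scale in `[0, 1]`; drawn uniformly if
#'   `NULL`.
#' @return A [dynamic_pet_image()] of the same shape.
#' @export
poisson_augment <- function(image, p = NULL) {
  stopifnot(inherits(image, "dynamic_pet_image"))
  if (is.null(p)) p <- stats::runif(1)
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]")
  if (p == 0) return(image)
  lam <- pmax(image$values, 0) * p
  noisy <- image$values + (stats::rpois(length(lam), lam) - lam)
  dim(noisy) <- dim(image$values)
  dynamic_pet_image(noisy, image$schedule, image$spacing)
}

#' Cross-validation folds
#'
#' Shuffles sample indices deterministically and splits them into `k`
#' validation sets whose sizes differ by at most one; the union of the
#' validation sets is all samples and they are pairwise disjoint.
#'
#' @param n_samples Number of samples (>= k).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return List of `k` lists with integer elements `train` and `val`.
#' @export
make_folds <- function(n_samples, k = 10L, seed = 1L) {
  if (n_samples < k) stop("`n_samples` must be at least `k`")
  perm <- withr::with_seed(as.integer(seed), sample.int(n_samples))
  grp <- rep(seq_len(k), length.out = n_samples)  # sizes differ by <= 1
  lapply(seq_len(k), function(f) {
    val <- sort(perm[grp == f])
    list(train = setdiff(seq_len(n_samples), val), val = val)
  })
}

#' Training configuration
#'
#' ADAM with the customary defaults (beta1 = 0.9, beta2 = 0.999,
#' eps = 1e-8, no weight decay), learning rate 1e-4, batch size 1, loss
#' [weighted_mse()], Poisson augmentation applied to every sample every
#' epoch when enabled.  1000 epochs is the full-scale setting; tests and
#' the synthetic recovery study use far fewer.
#'
#' @param learning_rate Positive step size.
#' @param epochs Positive integer.
#' @param augment Apply [poisson_augment()] each epoch.
#' @param shuffle Reshuffle sample order each epoch.
#' @param seed Integer seed controlling initialization order, shuffling and
#'   augmentation.
#' @param weights A [loss_weights()].
#' @param verbose Print the loss every `verbose` epochs (0 = silent).
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 1000L, augment = TRUE,
                         shuffle = TRUE, seed = 1L, weights = loss_weights(),
                         verbose = 0L) {
  if (learning_rate <= 0) stop("`learning_rate` must be positive")
  if (epochs < 1) stop("`epochs` must be positive")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 augment = isTRUE(augment), shuffle = isTRUE(shuffle),
                 seed = as.integer(seed), weights = weights,
                 verbose = as.integer(verbose)),
            class = "train_config")
}

#' Train a network on (image, input-function) pairs
#'
#' Stochastic gradient descent with ADAM, one image per step, minimizing
#' the segment-weighted MSE between the predicted and target curves.  Fully
#' reproducible for a fixed seed on one device.
#'
#' @param network An `fcdlif_network` (its weights are the starting point).
#' @param dataset Non-empty list; each element has `image`
#'   (a [dynamic_pet_image()], all with identical spatial shape) and `aif`
#'   (a [blood_curve()] target).  [generate_phantom()] outputs qualify.
#' @param config A [train_config()].
#' @return A list of class `fcdlif_fit`: `network` (trained), `history`
#'   (tibble epoch, loss with one row per epoch), `config`.
#' @export
train_network <- function(network, dataset, config = train_config()) {
  stopifnot(inherits(network, "fcdlif_network"), inherits(config, "train_config"))
  if (length(dataset) == 0L) stop("`dataset` must not be empty")
  shapes <- vapply(dataset, function(d) paste(dim(d$image$values)[2:4], collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L)
    stop("all images in `dataset` must share one spatial shape")
  p <- network$params
  m <- lapply(p, function(x) x * 0)
  v <- lapply(p, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  nms <- names(p)
  trainable <- nms[!network$frozen[nms]]
  history <- numeric(config$epochs)
  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- if (config$shuffle) sample.int(length(dataset)) else seq_along(dataset)
      epoch_loss <- 0
      for (i in ord) {
        smp <- dataset[[i]]
        img <- if (config$augment) poisson_augment(smp$image) else smp$image
        tmp_net <- network; tmp_net$params <- p
        fw <- network_forward(tmp_net, img$values, keep_cache = TRUE)
        target <- smp$aif$suv
        T <- length(target)
        if (length(fw$curve) != T) stop("curve/target length mismatch")
        w <- expand_loss_weights(config$weights, smp$aif$time_s)
        resid <- fw$curve - target
        epoch_loss <- epoch_loss + mean(w * resid^2)
        dcurve <- 2 * w * resid / T
        grads <- network_backward(tmp_net, fw$cache, dcurve)
        step <- step + 1L
        corr1 <- 1 - b1^step; corr2 <- 1 - b2^step
        for (nm in trainable) {
          g <- grads[[nm]]
          m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g
          v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g^2
          p[[nm]] <- p[[nm]] - config$learning_rate *
            (m[[nm]] / corr1) / (sqrt(v[[nm]] / corr2) + eps)
        }
      }
      history[epoch] <- epoch_loss / length(dataset)
      if (config$verbose > 0 && epoch %% config$verbose == 0)
        message(sprintf("epoch %4d  wMSE %.6g", epoch, history[epoch]))
    }
  })
  network$params <- p
  structure(list(network = network,
                 history = tibble::tibble(epoch = seq_len(config$epochs),
                                          loss = history),
                 config = config),
            class = "fcdlif_fit")
}

#' Save / load a trained network checkpoint
#'
#' The checkpoint is an RDS container holding the weights with the
#' configuration embedded.
#'
#' @param network An `fcdlif_network`.
#' @param path File path (`.rds`).
#' @return `load_network()` returns an `fcdlif_network`.
#' @export
save_network <- function(network, path) {
  stopifnot(inherits(network, "fcdlif_network"))
  saveRDS(network, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "fcdlif_network")) stop("not a network checkpoint: ", path)
  net
}
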