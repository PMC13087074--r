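# Forward and backward passes.  Activations travel as 3-D arrays
# (channels x voxels x frames); the voxel axis linearises (depth, height,
# width) column-major, matching both R arrays and the C++ kernels.

relu_ <- function(x) {
  x[x < 0] <- 0
  x
}

as_cube <- function(values) {
  # (time, d, h, w) array -> (1, nvox, T)
  d <- dim(values)
  arr <- aperm(values, c(2L, 3L, 4L, 1L))
  dim(arr) <- c(1L, prod(d[2:4]), d[1L])
  arr
}

proj_apply <- function(W, b, x) {
  d <- dim(x)
  y <- W %*% matrix(x, d[1L], d[2L] * d[3L]) + b
  dim(y) <- c(nrow(W), d[2L], d[3L])
  y
}

# Full forward pass; returns curve, features and (optionally) the cache
# needed for backprop.
network_forward <- function(network, values, keep_cache = FALSE) {
  cfg <- network$config
  p <- network$params
  spatial <- dim(values)[2:4]
  if (!all(spatial == cfg$input_shape))
    stop("spatial shape mismatch: image is ",
         paste(spatial, collapse = "x"), " but the network was built for ",
         paste(cfg$input_shape, collapse = "x"),
         " (only the temporal dimension is unconstrained)")
  plan <- sfe_plan(cfg)
  x <- as_cube(values)
  cache <- list(stages = vector("list", length(plan)))
  for (s in seq_along(plan)) {
    st <- plan[[s]]
    dims <- as.integer(st$dims)
    if (st$op == "pool") {
      r <- maxpool3d_fw(x, dims)
      if (keep_cache) cache$stages[[s]] <- list(idx = r$idx, n_in = prod(dims))
      x <- r$Y
    } else if (st$op == "block") {
      i <- st$index
      pre <- sprintf("sfe.block%d", i)
      k3 <- c(3L, 3L, 3L); pd <- c(1L, 1L, 1L)
      z1 <- conv3d_fw(x, p[[paste0(pre, ".conv1.W")]], p[[paste0(pre, ".conv1.b")]],
                      dims, k3, pd)
      a1 <- relu_(z1)
      z2 <- conv3d_fw(a1, p[[paste0(pre, ".conv2.W")]], p[[paste0(pre, ".conv2.b")]],
                      dims, k3, pd)
      has_proj <- !is.null(p[[paste0(pre, ".proj.W")]])
      s_ <- if (has_proj)
        proj_apply(p[[paste0(pre, ".proj.W")]], p[[paste0(pre, ".proj.b")]], x)
      else x
      z <- z2 + s_
      y <- relu_(z)
      if (keep_cache)
        cache$stages[[s]] <- list(x = x, a1 = a1, mask1 = z1 > 0, mask_out = z > 0,
                                  has_proj = has_proj)
      x <- y
    } else { # final valid conv + ReLU
      z3 <- conv3d_fw(x, p[["sfe.final.W"]], p[["sfe.final.b"]],
                      dims, cfg$final_kernel, c(0L, 0L, 0L))
      y3 <- relu_(z3)
      if (keep_cache) cache$stages[[s]] <- list(x = x, mask = z3 > 0)
      x <- y3
    }
  }
  n_cells <- dim(x)[2L]
  feats <- apply(x, c(1L, 3L), mean)           # (32 x T) global average pool
  if (is.null(dim(feats))) feats <- matrix(feats, nrow = cfg$feature_dim)
  tfe <- tfe_forward(network, feats, keep_cache)
  if (keep_cache) {
    cache$gap_n_cells <- n_cells
    cache$feats <- feats
    cache$tfe <- tfe$cache
  }
  list(curve = tfe$curve, features = t(feats), cache = if (keep_cache) cache)
}

conv1d_col <- function(F, k) {
  # (C x T) -> (C*k x T) with zero "same" padding; rows grouped by offset
  C <- nrow(F); T <- ncol(F); r <- (k - 1L) %/% 2L
  Fp <- cbind(matrix(0, C, r), F, matrix(0, C, r))
  col <- matrix(0, C * k, T)
  for (o in seq_len(k))
    col[((o - 1L) * C + 1L):(o * C), ] <- Fp[, o:(o + T - 1L), drop = FALSE]
  col
}

conv1d_col_bw <- function(dcol, C, k, T) {
  r <- (k - 1L) %/% 2L
  dFp <- matrix(0, C, T + 2L * r)
  for (o in seq_len(k))
    dFp[, o:(o + T - 1L)] <- dFp[, o:(o + T - 1L)] +
      dcol[((o - 1L) * C + 1L):(o * C), , drop = FALSE]
  dFp[, (r + 1L):(r + T), drop = FALSE]
}

tfe_forward <- function(network, feats, keep_cache = FALSE) {
  cfg <- network$config
  p <- network$params
  ch <- cfg$tfe_channels
  k <- cfg$tfe_kernel
  A <- feats
  cache <- list(inputs = list(), masks = list())
  n_layers <- length(ch) - 1L
  for (j in seq_len(n_layers)) {
    col <- conv1d_col(A, k)
    Z <- p[[sprintf("tfe.l%d.W", j)]] %*% col + p[[sprintf("tfe.l%d.b", j)]]
    if (keep_cache) cache$inputs[[j]] <- A
    if (j < n_layers) {
      if (keep_cache) cache$masks[[j]] <- Z > 0
      A <- relu_(Z)
    } else A <- Z
  }
  list(curve = as.vector(A), cache = if (keep_cache) cache)
}

# Backward pass.  `dcurve` is dLoss/dOutput (length T).  Returns gradients
# as a flat named list matching network$params.
network_backward <- function(network, cache, dcurve) {
  cfg <- network$config
  p <- network$params
  grads <- lapply(p, function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x)))
  ch <- cfg$tfe_channels
  k <- cfg$tfe_kernel
  n_layers <- length(ch) - 1L
  dA <- matrix(dcurve, nrow = 1L)
  for (j in rev(seq_len(n_layers))) {
    if (j < n_layers) dA <- dA * cache$tfe$masks[[j]]
    A_in <- cache$tfe$inputs[[j]]
    col <- conv1d_col(A_in, k)
    W <- p[[sprintf("tfe.l%d.W", j)]]
    grads[[sprintf("tfe.l%d.W", j)]] <- dA %*% t(col)
    grads[[sprintf("tfe.l%d.b", j)]] <- rowSums(dA)
    dcol <- t(W) %*% dA
    dA <- conv1d_col_bw(dcol, nrow(A_in), k, ncol(A_in))
  }
  # through the global average pool
  n_cells <- cache$gap_n_cells
  T <- ncol(dA)
  dX <- array(0, c(cfg$feature_dim, n_cells, T))
  for (t in seq_len(T)) dX[, , t] <- matrix(dA[, t] / n_cells, cfg$feature_dim, n_cells)
  plan <- sfe_plan(cfg)
  for (s in rev(seq_along(plan))) {
    st <- plan[[s]]
    dims <- as.integer(st$dims)
    cc <- cache$stages[[s]]
    if (st$op == "final") {
      dZ3 <- dX * cc$mask
      r <- conv3d_bw(cc$x, dZ3, p[["sfe.final.W"]], dims, cfg$final_kernel, c(0L, 0L, 0L))
      grads[["sfe.final.W"]] <- r$dW
      grads[["sfe.final.b"]] <- as.vector(r$db)
      dX <- r$dX
    } else if (st$op == "block") {
      i <- st$index
      pre <- sprintf("sfe.block%d", i)
      k3 <- c(3L, 3L, 3L); pd <- c(1L, 1L, 1L)
      dZ <- dX * cc$mask_out
      r2 <- conv3d_bw(cc$a1, dZ, p[[paste0(pre, ".conv2.W")]], dims, k3, pd)
      grads[[paste0(pre, ".conv2.W")]] <- r2$dW
      grads[[paste0(pre, ".conv2.b")]] <- as.vector(r2$db)
      dA1 <- r2$dX * cc$mask1
      r1 <- conv3d_bw(cc$x, dA1, p[[paste0(pre, ".conv1.W")]], dims, k3, pd)
      grads[[paste0(pre, ".conv1.W")]] <- r1$dW
      grads[[paste0(pre, ".conv1.b")]] <- as.vector(r1$db)
      dXin <- r1$dX
      if (cc$has_proj) {
        Wp <- p[[paste0(pre, ".proj.W")]]
        d <- dim(dZ)
        dZm <- matrix(dZ, d[1L], d[2L] * d[3L])
        xm <- matrix(cc$x, dim(cc$x)[1L], d[2L] * d[3L])
        grads[[paste0(pre, ".proj.W")]] <- dZm %*% t(xm)
        grads[[paste0(pre, ".proj.b")]] <- rowSums(dZm)
        dskip <- t(Wp) %*% dZm
        dim(dskip) <- dim(cc$x)
        dXin <- dXin + dskip
      } else {
        dXin <- dXin + dZ
      }
      dX <- dXin
    } else { # pool
      if (s == 1L) break  # nothing below the input pool needs gradients
      dX <- maxpool3d_bw(dX, cc$idx, cc$n_in)
    }
  }
  grads
}

#' Predict the input function for a dynamic PET image
#'
#' Runs the network on every time frame and returns the predicted blood
#' curve (DLIF) sampled at the frame midpoints of the image's schedule.
#' The image must match the spatial shape the network was built for; any
#' number of time frames is accepted.
#'
#' @param network An `fcdlif_network`.
#' @param image A [dynamic_pet_image()].
#' @return A [blood_curve()] of length `n_frames(image)`.
#' @export
predict_aif <- function(network, image) {
  stopifnot(inherits(network, "fcdlif_network"), inherits(image, "dynamic_pet_image"))
  out <- network_forward(network, image$values)
  blood_curve(image$schedule$midpoint_s, out$curve)
}

#' Extract the per-frame spatial feature matrix
#'
#' Row `t` is the 32-dimensional SFE embedding of frame `t` alone: the SFE
#' is a pure per-frame map with weights shared across time, so permuting
#' frames permutes rows identically and perturbing one frame changes only
#' its own row.
#'
#' @param network An `fcdlif_network`.
#' @param image A [dynamic_pet_image()].
#' @return Numeric matrix `(T x feature_dim)`.
#' @export
extract_features <- function(network, image) {
  stopifnot(inherits(network, "fcdlif_network"), inherits(image, "dynamic_pet_image"))
  network_forward(network, image$values)$features
}
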