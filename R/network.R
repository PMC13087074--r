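#' Network configuration
#'
#' The input-function predictor has two parts.  A spatial feature extractor
#' (SFE) — a small 3D residual network with weights shared across time — is
#' applied to every time frame independently: an input max-pool, then
#' residual blocks (two same-padded 3x3x3 convolutions plus a skip, ReLU
#' activations, no normalization) interleaved with 2x2x2 max-pools, a final
#' valid convolution with a 4x2x2 cuboid kernel, and adaptive average
#' pooling down to a single spatial cell, yielding a 32-feature vector per
#' frame.  A temporal feature extractor (TFE) then applies zero-padded
#' "same" 1D convolutions along the frame axis, collapsing 32 channels to
#' one, so the output curve always has exactly as many samples as the input
#' has frames — the network is agnostic to the number of time frames.
#'
#' The shipped default (channel widths 12, 4, 24; TFE 32-41-222-1 with
#' kernel 5) has exactly 90124 trainable parameters.  The widths are one
#' admissible member of the family fixed by that budget (the architecture
#' skeleton plus a total-parameter constraint does not pin down widths
#' uniquely); the configuration search that produced them ships in
#' `tools/width_search.R`.  The second block is deliberately the narrowest,
#' keeping early full-resolution compute low and deferring temporal
#' modelling entirely to the TFE.
#'
#' @param input_shape Spatial shape `(depth, height, width)` the SFE is
#'   built for; inference requires exactly this shape (the temporal length
#'   is unconstrained).
#' @param block_channels Output channels of the residual blocks.
#' @param pool_input Max-pool the raw frame before the first block.
#' @param pool_after Logical per block: max-pool after that block.
#' @param final_kernel Kernel of the final valid SFE convolution.
#' @param feature_dim Per-frame feature vector length (32).
#' @param tfe_channels Channel schedule of the TFE; must start at
#'   `feature_dim` and end at 1.
#' @param tfe_kernel Odd temporal kernel width.
#' @param activation Only `"relu"` is implemented.
#' @param norm Only `"none"` is implemented.
#' @return A `network_config` object.
#' @export
network_config <- function(input_shape = c(96L, 48L, 48L),
                           block_channels = c(12L, 4L, 24L),
                           pool_input = TRUE,
                           pool_after = c(TRUE, TRUE, FALSE),
                           final_kernel = c(4L, 2L, 2L),
                           feature_dim = 32L,
                           tfe_channels = c(32L, 41L, 222L, 1L),
                           tfe_kernel = 5L,
                           activation = "relu",
                           norm = "none") {
  cfg <- list(input_shape = as.integer(input_shape),
              block_channels = as.integer(block_channels),
              pool_input = isTRUE(pool_input),
              pool_after = as.logical(pool_after),
              final_kernel = as.integer(final_kernel),
              feature_dim = as.integer(feature_dim),
              tfe_channels = as.integer(tfe_channels),
              tfe_kernel = as.integer(tfe_kernel),
              activation = match.arg(activation, "relu"),
              norm = match.arg(norm, "none"))
  if (length(cfg$input_shape) != 3L || any(cfg$input_shape < 1L))
    stop("`input_shape` must be three positive integers")
  if (length(cfg$block_channels) < 1L || any(cfg$block_channels < 1L))
    stop("`block_channels` must be positive integers")
  if (length(cfg$pool_after) != length(cfg$block_channels))
    stop("`pool_after` must have one entry per block")
  if (cfg$tfe_kernel %% 2L != 1L) stop("`tfe_kernel` must be odd")
  if (cfg$tfe_channels[1L] != cfg$feature_dim)
    stop("`tfe_channels` must start at `feature_dim`")
  if (cfg$tfe_channels[length(cfg$tfe_channels)] != 1L)
    stop("`tfe_channels` must end at 1")
  if (cfg$block_channels[min(2L, length(cfg$block_channels))] > cfg$block_channels[1L])
    stop("the second block must not be wider than the first")
  # walk the spatial cascade to make sure pooling and the final kernel fit
  sfe_plan(cfg)
  structure(cfg, class = "network_config")
}

#' @rdname network_config
#' @export
reduced_network_config <- function() network_config(input_shape = c(32L, 16L, 16L))

#' Read / write a network configuration as YAML
#'
#' @param config A [network_config()].
#' @param path YAML file path.
#' @return `read_network_config()` returns a [network_config()].
#' @export
write_network_config <- function(config, path) {
  stopifnot(inherits(config, "network_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  do.call(network_config, yaml::read_yaml(path))
}

# Spatial cascade bookkeeping: dims entering each stage.
sfe_plan <- function(cfg) {
  dims <- cfg$input_shape
  halve <- function(dims, where) {
    if (any(dims %% 2L != 0L))
      stop("spatial shape incompatible with the pooling cascade at ", where,
           " (dims ", paste(dims, collapse = "x"), " not even)")
    dims %/% 2L
  }
  plan <- list()
  if (cfg$pool_input) {
    plan[[length(plan) + 1L]] <- list(op = "pool", dims = dims)
    dims <- halve(dims, "input pool")
  }
  for (i in seq_along(cfg$block_channels)) {
    plan[[length(plan) + 1L]] <- list(op = "block", index = i, dims = dims)
    if (cfg$pool_after[i]) {
      plan[[length(plan) + 1L]] <- list(op = "pool", dims = dims)
      dims <- halve(dims, paste0("pool after block ", i))
    }
  }
  if (any(dims < cfg$final_kernel))
    stop("spatial shape incompatible: ", paste(dims, collapse = "x"),
         " is smaller than the final ", paste(cfg$final_kernel, collapse = "x"),
         " kernel")
  plan[[length(plan) + 1L]] <- list(op = "final", dims = dims,
                                    dims_out = dims - cfg$final_kernel + 1L)
  plan
}

he_init <- function(n_out, fan_in, n_w) {
  matrix(stats::rnorm(n_out * n_w, sd = sqrt(2 / fan_in)), nrow = n_out)
}

#' Build a network from a configuration
#'
#' Weights use He initialization (suited to ReLU); biases start at zero.
#'
#' @param config A [network_config()].
#' @param seed Optional integer seed for reproducible initialization
#'   (isolated from the session RNG).
#' @return An `fcdlif_network` object.
#' @export
build_network <- function(config, seed = NULL) {
  stopifnot(inherits(config, "network_config"))
  make <- function() {
    params <- list()
    in_ch <- 1L
    for (i in seq_along(config$block_channels)) {
      out_ch <- config$block_channels[i]
      pre <- sprintf("sfe.block%d", i)
      params[[paste0(pre, ".conv1.W")]] <- he_init(out_ch, in_ch * 27L, in_ch * 27L)
      params[[paste0(pre, ".conv1.b")]] <- numeric(out_ch)
      params[[paste0(pre, ".conv2.W")]] <- he_init(out_ch, out_ch * 27L, out_ch * 27L)
      params[[paste0(pre, ".conv2.b")]] <- numeric(out_ch)
      if (in_ch != out_ch) {
        params[[paste0(pre, ".proj.W")]] <- he_init(out_ch, in_ch, in_ch)
        params[[paste0(pre, ".proj.b")]] <- numeric(out_ch)
      }
      in_ch <- out_ch
    }
    kf <- prod(config$final_kernel)
    params[["sfe.final.W"]] <- he_init(config$feature_dim, in_ch * kf, in_ch * kf)
    params[["sfe.final.b"]] <- numeric(config$feature_dim)
    ch <- config$tfe_channels
    for (j in seq_len(length(ch) - 1L)) {
      pre <- sprintf("tfe.l%d", j)
      fan <- ch[j] * config$tfe_kernel
      params[[paste0(pre, ".W")]] <- he_init(ch[j + 1L], fan, fan)
      params[[paste0(pre, ".b")]] <- numeric(ch[j + 1L])
    }
    params
  }
  params <- if (is.null(seed)) make() else withr::with_seed(as.integer(seed), make())
  structure(list(config = config, params = params,
                 frozen = stats::setNames(rep(FALSE, length(params)), names(params))),
            class = "fcdlif_network")
}

#' Count network parameters
#'
#' @param network An `fcdlif_network`.
#' @param trainable_only Count only parameters not marked frozen (default).
#' @return Integer total number of weights and biases.
#' @examples
#' \donttest{
#' net <- build_network(network_config(), seed = 1)
#' count_parameters(net)  # 90124
#' }
#' @export
count_parameters <- function(network, trainable_only = TRUE) {
  stopifnot(inherits(network, "fcdlif_network"))
  keep <- if (trainable_only) !network$frozen else rep(TRUE, length(network$params))
  sum(vapply(network$params[keep], length, integer(1)))
}

#' Freeze or unfreeze all parameters
#'
#' @param network An `fcdlif_network`.
#' @param frozen Logical.
#' @return The network with its frozen flags set.
#' @export
freeze_network <- function(network, frozen = TRUE) {
  stopifnot(inherits(network, "fcdlif_network"))
  network$frozen[] <- frozen
  network
}

#' Per-layer summary table
#'
#' @param network An `fcdlif_network`.
#' @return A tibble with columns `layer`, `shape`, `n_params`.
#' @export
describe_network <- function(network) {
  stopifnot(inherits(network, "fcdlif_network"))
  tibble::tibble(
    layer = names(network$params),
    shape = vapply(network$params, function(p)
      paste(if (is.matrix(p)) dim(p) else length(p), collapse = "x"), character(1)),
    n_params = vapply(network$params, length, integer(1)))
}

#' @export
print.fcdlif_network <- function(x, ...) {
  cat(sprintf("<fcdlif_network> input %s (any frame count), %d trainable parameters\n",
              paste(x$config$input_shape, collapse = "x"), count_parameters(x)))
  invisible(x)
}
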