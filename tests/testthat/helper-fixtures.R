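# Shared fixtures, built once per test run.  Everything is generated in
# code; nothing is read from disk.

# Noiseless reduced-resolution phantom with known ground truth.
fixture_phantom <- local({
  ph <- NULL
  function() {
    if (is.null(ph)) ph <<- generate_phantom(phantom_spec(noise_scale = 0), seed = 301)
    ph
  }
})

# Untrained reduced-scale network with a fixed seed.
fixture_net <- local({
  net <- NULL
  function() {
    if (is.null(net)) net <<- build_network(reduced_network_config(), seed = 77)
    net
  }
})

# A tiny configuration small enough for numerical gradient checking.
tiny_config <- function() {
  network_config(input_shape = c(8L, 4L, 4L), block_channels = c(2L, 2L, 3L),
                 pool_after = c(FALSE, FALSE, FALSE), final_kernel = c(4L, 2L, 2L),
                 feature_dim = 4L, tfe_channels = c(4L, 3L, 1L), tfe_kernel = 3L)
}

random_image <- function(n_frames, shape, seed = 1, schedule = NULL) {
  if (is.null(schedule))
    schedule <- frame_schedule(seq(0, by = 10, length.out = n_frames),
                               rep(10, n_frames))
  withr::with_seed(seed, {
    vals <- array(abs(stats::rnorm(n_frames * prod(shape))), c(n_frames, shape))
    dynamic_pet_image(vals, schedule)
  })
}
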