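test_that("the shipped default configuration has exactly the published parameter budget", {
  net <- build_network(network_config(), seed = 1)
  expect_identical(count_parameters(net), 90124L)
  # the reduced-resolution twin shares the topology, hence the budget
  expect_identical(count_parameters(build_network(reduced_network_config(), seed = 1)),
                   90124L)
  # per-layer table sums to the same total
  expect_identical(sum(describe_network(net)$n_params), 90124L)
})

test_that("parameter counting follows weights + biases and respects freezing", {
  # a single 1D convolution, 32 -> 1 channels, kernel 3, with bias: 32*1*3 + 1
  cfg <- network_config(input_shape = c(8L, 4L, 4L), block_channels = c(1L, 1L, 1L),
                        pool_after = c(FALSE, FALSE, FALSE),
                        final_kernel = c(4L, 2L, 2L), feature_dim = 32L,
                        tfe_channels = c(32L, 1L), tfe_kernel = 3L)
  net <- build_network(cfg, seed = 1)
  expect_identical(length(net$params[["tfe.l1.W"]]) + length(net$params[["tfe.l1.b"]]),
                   97L)
  frozen <- freeze_network(net)
  expect_identical(count_parameters(frozen), 0L)
  expect_identical(count_parameters(frozen, trainable_only = FALSE),
                   count_parameters(net))
})

test_that("output length always equals input frame count", {
  net <- fixture_net()
  for (T in c(1L, 5L, 36L, 42L, 43L)) {
    img <- random_image(T, c(32, 16, 16), seed = T)
    curve <- predict_aif(net, img)
    expect_equal(nrow(curve), T)
    expect_true(all(is.finite(curve$suv)))
    expect_equal(curve$time_s, img$schedule$midpoint_s)
  }
})

test_that("the canonical-resolution network maps a 42-frame scan to a 42-point curve", {
  net <- build_network(network_config(), seed = 2)
  img <- dynamic_pet_image(array(0.5, c(42, 96, 48, 48)), canonical_schedule())
  curve <- predict_aif(net, img)
  expect_equal(nrow(curve), 42L)
  expect_true(all(is.finite(curve$suv)))
})

test_that("a spatial shape mismatch is an error, zero input is numerically safe", {
  net <- fixture_net()
  img <- random_image(3, c(16, 16, 16), seed = 1)
  expect_error(predict_aif(net, img), "spatial shape mismatch")
  zero <- dynamic_pet_image(array(0, c(4, 32, 16, 16)),
                            frame_schedule(c(0, 30, 60, 90), rep(30, 4)))
  curve <- predict_aif(net, zero)
  expect_true(all(is.finite(curve$suv)))
})

test_that("the spatial extractor is a pure per-frame map with shared weights", {
  net <- fixture_net()
  img <- random_image(6, c(32, 16, 16), seed = 21)
  f <- extract_features(net, img)
  expect_identical(dim(f), c(6L, 32L))
  # permuting frames permutes feature rows identically
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  img_p <- dynamic_pet_image(img$values[perm, , , , drop = FALSE], img$schedule)
  expect_equal(extract_features(net, img_p), f[perm, ])
  # perturbing one frame changes only its own row
  img2 <- img
  img2$values[4, , , ] <- img2$values[4, , , ] + 1
  f2 <- extract_features(net, img2)
  expect_equal(f2[-4, ], f[-4, ])
  expect_false(isTRUE(all.equal(f2[4, ], f[4, ])))
  # identical frames embed identically
  vals <- array(0, c(6, 32, 16, 16))
  for (t in 1:6) vals[t, , , ] <- img$values[1, , , ]
  same <- dynamic_pet_image(vals, img$schedule)
  fs <- extract_features(net, same)
  expect_equal(fs, matrix(fs[1, ], 6, 32, byrow = TRUE))
})

test_that("backpropagated gradients match numerical differentiation", {
  net <- build_network(tiny_config(), seed = 3)
  withr::with_seed(4, {
    x <- array(stats::rnorm(6 * 8 * 4 * 4), c(6, 8, 4, 4))
    target <- stats::rnorm(6)
  })
  w <- rep(1, 6)
  loss <- function(n) {
    fw <- fcdlif:::network_forward(n, x)
    mean(w * (fw$curve - target)^2)
  }
  fw <- fcdlif:::network_forward(net, x, keep_cache = TRUE)
  grads <- fcdlif:::network_backward(net, fw$cache,
                                     2 * w * (fw$curve - target) / 6)
  eps <- 1e-6
  withr::with_seed(5, {
    for (nm in names(net$params)) {
      for (i in sample(length(net$params[[nm]]), min(3, length(net$params[[nm]])))) {
        n1 <- net; n1$params[[nm]][i] <- n1$params[[nm]][i] + eps
        n2 <- net; n2$params[[nm]][i] <- n2$params[[nm]][i] - eps
        num <- (loss(n1) - loss(n2)) / (2 * eps)
        expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
      }
    }
  })
})

test_that("network configurations survive a YAML round trip", {
  cfg <- reduced_network_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_network_config(cfg, path)
  expect_equal(read_network_config(path), cfg)
})

test_that("configurations violating the architecture contract are rejected", {
  expect_error(network_config(tfe_kernel = 4L), "odd")
  expect_error(network_config(tfe_channels = c(32L, 16L, 2L)), "end at 1")
  expect_error(network_config(tfe_channels = c(16L, 1L)), "feature_dim")
  expect_error(network_config(block_channels = c(4L, 12L, 24L),
                              pool_after = c(TRUE, TRUE, FALSE)),
               "second block")
  # 96 is not divisible by 2 four times with the final kernel still fitting
  expect_error(network_config(input_shape = c(6L, 6L, 6L)), "incompatible")
})
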