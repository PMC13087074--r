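test_that("phantom generation is bit-identical for a fixed seed", {
  spec <- phantom_spec()
  a <- generate_phantom(spec, seed = 9)
  b <- generate_phantom(spec, seed = 9)
  expect_identical(a$image$values, b$image$values)
  expect_identical(a$aif$suv, b$aif$suv)
  c <- generate_phantom(spec, seed = 10)
  expect_false(identical(a$image$values, c$image$values))
})

test_that("noiseless blood-pool voxels carry exactly the frame-averaged input function", {
  ph <- fixture_phantom()
  bp <- ph$masks == 1L
  expect_gt(sum(bp), 0)
  truth <- frame_average(aif_function(ph$spec$aif), ph$spec$schedule)
  for (t in c(1L, 7L, 26L, 42L)) {
    frame <- ph$image$values[t, , , ]
    expect_equal(unique(as.vector(frame[bp])), truth$suv[t])
  }
  expect_equal(ph$aif$suv, truth$suv)
})

test_that("an empty phantom yields an all-zero image", {
  spec <- phantom_spec(organs = list(),
                       background = kinetic_params(K1 = 0, k2 = 0, k3 = 0, vB = 0),
                       aif = aif_params(A1 = 0, A2 = 0, A3 = 0),
                       noise_scale = 0)
  ph <- generate_phantom(spec, seed = 1)
  expect_true(all(ph$image$values == 0))
})

test_that("noiseless images are non-negative and finite", {
  ph <- fixture_phantom()
  expect_true(all(is.finite(ph$image$values)))
  expect_true(all(ph$image$values >= 0))
})

test_that("count noise preserves the expected value within Monte-Carlo error", {
  # a uniform background region gives >1e4 iid voxel realizations per frame
  spec <- phantom_spec(grid_shape = c(32, 20, 20), organs = list(), noise_scale = 5)
  noiseless <- generate_phantom(
    phantom_spec(grid_shape = c(32, 20, 20), organs = list(), noise_scale = 0),
    seed = 1)
  noisy <- generate_phantom(spec, seed = 2)
  bg <- noisy$masks == 0L
  expect_gt(sum(bg), 10000)
  for (t in c(2L, 30L, 42L)) {
    mu <- unique(as.vector(noiseless$image$values[t, , , ][bg]))
    draws <- as.vector(noisy$image$values[t, , , ][bg])
    se <- stats::sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - mu), 3 * se + 1e-12)
  }
})

test_that("longer frames are less noisy: the coefficient of variation falls with duration", {
  spec <- phantom_spec(organs = list(), noise_scale = 5)
  ph <- generate_phantom(spec, seed = 3)
  bg <- ph$masks == 0L
  sched <- ph$spec$schedule
  cv <- vapply(seq_len(42), function(t) {
    v <- as.vector(ph$image$values[t, , , ][bg])
    stats::sd(v) / mean(v)
  }, numeric(1))
  cv5 <- mean(cv[sched$duration_s == 5])
  cv20 <- mean(cv[sched$duration_s == 20])
  cv300 <- mean(cv[sched$duration_s == 300])
  expect_gt(cv5, cv20)
  expect_gt(cv20, cv300)
})

test_that("overlapping organs warn and the last writer wins", {
  spec <- phantom_spec(organs = list(
    a = list(center = c(16, 8, 8), axes = c(3, 3, 3),
             kinetics = kinetic_params(K1 = 0.3, k2 = 0.5, k3 = 0.02, vB = 0)),
    b = list(center = c(16, 8, 8), axes = c(2, 2, 2),
             kinetics = kinetic_params(K1 = 0.9, k2 = 0.8, k3 = 0.2, vB = 0))),
    noise_scale = 0)
  expect_warning(ph <- generate_phantom(spec, seed = 1), "overlap")
  expect_equal(ph$masks[16, 8, 8], 3L)  # organ b is label 3 (after blood pool)
})

test_that("phantom specs survive a YAML round trip", {
  spec <- phantom_spec()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_phantom_spec(spec, path)
  back <- read_phantom_spec(path)
  expect_equal(back$grid_shape, spec$grid_shape)
  expect_equal(unclass(back$aif), unclass(spec$aif), tolerance = 1e-12)
  expect_equal(back$schedule, spec$schedule)
  expect_equal(unclass(back$organs$myocardium$kinetics),
               unclass(spec$organs$myocardium$kinetics))
})

test_that("sampled phantom families are deterministic and within jitter ranges", {
  specs1 <- sample_phantom_specs(5, seed = 4)
  specs2 <- sample_phantom_specs(5, seed = 4)
  expect_equal(specs1, specs2)
  base <- phantom_spec()
  for (sp in specs1) {
    expect_true(sp$aif$A1 >= 0.7 * base$aif$A1 && sp$aif$A1 <= 1.3 * base$aif$A1)
    expect_true(sp$aif$t0 >= 0 && sp$aif$t0 <= 15)
  }
})
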