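test_that("the segment-weighted MSE reproduces hand-worked values", {
  t42 <- canonical_schedule()$midpoint_s
  zero <- blood_curve(t42, rep(0, 42))
  expect_equal(weighted_mse(zero, zero), 0)
  # constant +1 error: (25*0.4 + 9*0.7 + 8*1.0)/42 = 24.3/42
  expect_equal(weighted_mse(blood_curve(t42, rep(1, 42)), zero), 24.3 / 42)
  # +1 on the 8 tail frames only: 8/42
  tail_err <- rep(0, 42); tail_err[35:42] <- 1
  expect_equal(weighted_mse(blood_curve(t42, tail_err), zero), 8 / 42)
  expect_error(weighted_mse(rep(1, 41), rep(0, 42)), "length mismatch")
})

test_that("unit weights reduce the loss to the plain evaluation MSE", {
  withr::with_seed(6, {
    a <- blood_curve(canonical_schedule()$midpoint_s, stats::runif(42, 0, 10))
    b <- blood_curve(canonical_schedule()$midpoint_s, stats::runif(42, 0, 10))
  })
  expect_equal(weighted_mse(a, b, weights = NULL), mean((a$suv - b$suv)^2))
  expect_equal(weighted_mse(a, b, weights = NULL), compare_curves(a, b)$mse)
})

test_that("off-schedule curves are segmented by the canonical time boundaries", {
  # canonical 42-frame curves use the 25/9/8 count split
  lab42 <- segment_labels(canonical_schedule()$midpoint_s)
  expect_equal(as.vector(table(lab42)), c(25, 9, 8))
  # a truncated 32-frame curve falls back to the time thresholds
  tt <- subset_schedule(canonical_schedule(), 5:36)$midpoint_s + 45
  lab <- segment_labels(tt)
  expect_equal(as.character(unique(lab[tt < 150])), "peak")
  expect_equal(as.character(unique(lab[tt >= 150 & tt < 330])), "intermediate")
  expect_equal(as.character(unique(lab[tt >= 330])), "tail")
})

test_that("count-noise augmentation is an identity at p = 0 and preserves zeros", {
  img <- fixture_phantom()$image
  expect_identical(poisson_augment(img, p = 0)$values, img$values)
  zimg <- dynamic_pet_image(array(0, c(2, 4, 4, 4)),
                            frame_schedule(c(0, 30), c(30, 30)))
  withr::with_seed(1, out <- poisson_augment(zimg))
  expect_identical(out$values, zimg$values)
})

test_that("augmentation moments match the Poisson model at fixed p", {
  # I = 10, p = 0.5: mean 10, variance I*p = 5, checked over 1e5 draws
  n <- 100000L
  img <- dynamic_pet_image(array(10, c(1, 50, 50, 40)),
                           frame_schedule(0, 30))
  withr::with_seed(8, out <- poisson_augment(img, p = 0.5))
  draws <- as.vector(out$values)
  expect_equal(length(draws), n)
  se_mean <- sqrt(5 / n)
  expect_lt(abs(mean(draws) - 10), 3 * se_mean)
  # SE of the variance estimate of Pois(5): sqrt((mu4 - var^2)/n), mu4 = lam(1+3lam)
  se_var <- sqrt((5 * 16 - 25) / n)
  expect_lt(abs(stats::var(draws) - 5), 3 * se_var)
})

test_that("cross-validation folds partition the samples evenly and reproducibly", {
  folds <- make_folds(70, k = 10, seed = 3)
  expect_length(folds, 10L)
  sizes <- vapply(folds, function(f) length(f$val), integer(1))
  expect_true(all(sizes == 7L))
  all_val <- sort(unlist(lapply(folds, `[[`, "val")))
  expect_identical(all_val, 1:70)
  for (f in folds) expect_length(intersect(f$train, f$val), 0L)
  expect_identical(folds, make_folds(70, k = 10, seed = 3))
  expect_false(identical(folds, make_folds(70, k = 10, seed = 4)))
  expect_error(make_folds(5, k = 10), "at least")
})

test_that("a short optimization run reduces the training loss deterministically", {
  specs <- sample_phantom_specs(3, phantom_spec(noise_scale = 0), seed = 30)
  ds <- lapply(seq_along(specs), function(i) generate_phantom(specs[[i]], seed = 30 + i))
  net <- build_network(reduced_network_config(), seed = 31)
  cfg <- train_config(learning_rate = 1e-3, epochs = 6, augment = FALSE, seed = 32)
  fit1 <- train_network(net, ds, cfg)
  expect_equal(nrow(fit1$history), 6L)
  expect_lt(fit1$history$loss[6], fit1$history$loss[1])
  fit2 <- train_network(net, ds, cfg)
  expect_identical(fit1$history$loss, fit2$history$loss)
  expect_identical(fit1$network$params, fit2$network$params)
  expect_error(train_network(net, list(), cfg), "empty")
})
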