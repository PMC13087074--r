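test_that("curve comparison reproduces hand-worked metrics", {
  tt <- seq(30, 150, by = 30)
  a <- blood_curve(tt, c(1, 4, 2, 6, 3))
  b <- blood_curve(tt, c(2, 3, 2, 8, 2))
  cmp <- compare_curves(a, b)
  expect_equal(cmp$mse, mean(c(1, 1, 0, 4, 1)))  # direct arithmetic
  expect_equal(cmp$r, stats::cor(a$suv, b$suv))
  expect_equal(cmp$r2, cmp$r^2)
  # identical curves: zero error; constant curves flag r as undefined
  same <- compare_curves(a, a)
  expect_equal(same$mse, 0)
  flat <- blood_curve(tt, rep(2, 5))
  expect_true(is.na(compare_curves(flat, flat)$r))
  # constant offset: MSE 1, perfect correlation
  off <- compare_curves(blood_curve(tt, b$suv + 1), b)
  expect_equal(off$mse, 1)
  expect_equal(off$r, 1)
  expect_error(compare_curves(a, blood_curve(tt + 1, b$suv)), "time grid")
})

test_that("quantile-quantile pairs are monotone in both coordinates", {
  withr::with_seed(12, {
    a <- blood_curve(1:50, stats::rlnorm(50))
    b <- blood_curve(1:50, stats::rlnorm(50))
  })
  qq <- compare_curves(a, b)$qq
  expect_true(!is.unsorted(qq$predicted_q))
  expect_true(!is.unsorted(qq$measured_q))
})

test_that("orthogonal regression is exact on collinear data and symmetric at ratio 1", {
  d <- deming_regression(c(1, 2, 3), c(2, 4, 6))
  expect_equal(d$slope, 2)
  expect_equal(d$intercept, 0)
  # swapping x and y reciprocates the slope at variance ratio 1
  withr::with_seed(13, {
    x <- stats::rnorm(60)
    y <- 1.8 * x + stats::rnorm(60, sd = 0.4)
  })
  expect_equal(deming_regression(x, y)$slope,
               1 / deming_regression(y, x)$slope, tolerance = 1e-12)
  # a point set symmetric under swapping x and y must fit slope 1 exactly
  base <- 1:10
  xs <- c(base + 0.5, base)
  ys <- c(base, base + 0.5)
  expect_equal(deming_regression(xs, ys)$slope, 1, tolerance = 1e-12)
  expect_error(deming_regression(rep(1, 5), rep(1, 5)), "identical")
})

test_that("orthogonal regression approaches ordinary least squares as the variance ratio grows", {
  withr::with_seed(14, {
    x <- stats::rnorm(80)
    y <- 0.7 * x + stats::rnorm(80, sd = 0.5)
  })
  ols <- unname(stats::coef(stats::lm(y ~ x))[2])
  expect_equal(deming_regression(x, y, variance_ratio = 1e10)$slope, ols,
               tolerance = 1e-6)
})

test_that("best/median/worst ranking follows ascending MSE with index tie-breaks", {
  r <- rank_samples(c(3, 1, 2))
  expect_equal(r, list(best = 2L, median = 3L, worst = 1L))
  one <- rank_samples(5)
  expect_equal(one$best, 1L); expect_equal(one$median, 1L); expect_equal(one$worst, 1L)
  ties <- rank_samples(c(2, 1, 1, 2))
  expect_equal(ties$best, 2L)   # lower index wins the tie
  expect_equal(ties$worst, 1L)
  expect_error(rank_samples(list()), "empty")
})

test_that("per-frame t-tests across a dataset report unadjusted and Bonferroni p-values", {
  tt <- canonical_schedule()$midpoint_s
  withr::with_seed(15, {
    measured <- lapply(1:8, function(i) blood_curve(tt, stats::runif(42, 1, 5)))
    predicted <- lapply(measured, function(b)
      blood_curve(tt, b$suv + stats::rnorm(42, sd = 0.2)))
  })
  res <- frame_ttests(predicted, measured)
  expect_equal(nrow(res), 42L)
  bonf <- frame_ttests(predicted, measured, p_adjust = "bonferroni")
  expect_true(all(bonf$p_value >= res$p_value - 1e-15))
})

test_that("prepending a frame lengthens the prediction by one and shifts it covariantly", {
  net <- fixture_net()
  ph <- fixture_phantom()
  res <- shift_test(net, ph$image, mode = "empty")
  expect_equal(nrow(res$shifted), nrow(res$original) + 1L)
  # interior shift-covariance: beyond the TFE receptive radius the shifted
  # output reproduces the original exactly (same-padded convolutions)
  radius <- with(fixture_net()$config,
                 (length(tfe_channels) - 1L) * (tfe_kernel - 1L) %/% 2L)
  dev <- abs(res$shifted$suv[-1L] - res$original$suv)
  expect_lt(max(dev[-seq_len(radius)]), 1e-10)
  # the copy mode also extends the curve
  res2 <- shift_test(net, ph$image, mode = "copy")
  expect_equal(nrow(res2$shifted), 43L)
})

test_that("truncation removes 4 early and 6 late frames and re-anchors the clock", {
  net <- fixture_net()
  ph <- fixture_phantom()
  res <- truncate_test(net, ph$image)
  expect_equal(nrow(res$truncated), 32L)
  expect_equal(res$retained_frames, 5:36)
  # the dropped tail spans 30 minutes
  dropped <- ph$image$schedule$duration_s[37:42]
  expect_equal(sum(dropped), 1800)
  expect_equal(res$truncated$time_s[1], ph$image$schedule$midpoint_s[5] -
                 ph$image$schedule$start_s[5])
  expect_error(truncate_test(net, random_image(9, c(32, 16, 16))), "too few")
})

test_that("the t-SNE embedding is deterministic and separates well-separated clusters", {
  withr::with_seed(16, {
    f1 <- matrix(stats::rnorm(40 * 32), 40)
    f2 <- matrix(stats::rnorm(40 * 32, mean = 8), 40)
  })
  emb <- tsne_features(rbind(f1, f2), seed = 17)
  expect_equal(dim(emb), c(80L, 4L))
  expect_identical(emb, tsne_features(rbind(f1, f2), seed = 17))
  skip_if_not_installed("cluster")
  sil <- cluster::silhouette(rep(1:2, each = 40),
                             stats::dist(cbind(emb$dim1, emb$dim2)))
  expect_gt(mean(sil[, 3]), 0.5)
  expect_error(tsne_features(f1[1:3, ]), "at least 5")
})

test_that("segment labels attached to embeddings partition the canonical frames 25/9/8", {
  net <- fixture_net()
  ph <- fixture_phantom()
  f <- extract_features(net, ph$image)
  emb <- tsne_features(list(s1 = f), times = ph$image$schedule$midpoint_s,
                       seed = 18, n_iter = 50)
  expect_equal(as.vector(table(emb$segment)), c(25, 9, 8))
  expect_equal(unique(emb$group), "s1")
})
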