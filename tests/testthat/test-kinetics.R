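sim_grid_tissue <- function(kp, plasma, times) {
  # forward simulation through the package's reference ODE solver, driven
  # by the piecewise-linear plasma the fitters also see
  pf <- stats::approxfun(c(0, plasma$time_s), c(0, plasma$suv), rule = 2)
  blood_curve(times, simulate_2tcm(kp, pf, times))
}

test_that("plasma conversion scales pointwise and flips the curve kind", {
  wb <- fixture_phantom()$aif
  p1 <- blood_to_plasma(wb, 1)
  expect_equal(p1$suv, wb$suv)
  expect_identical(curve_kind(p1), "plasma")
  pr <- blood_to_plasma(wb, 1.6)
  expect_equal(pr$suv, wb$suv * 1.6)
  expect_error(blood_to_plasma(p1, 1), "already a plasma")
  expect_error(blood_to_plasma(wb, -2), "positive")
})

test_that("a tabulated ratio is interpolated linearly in time", {
  wb <- blood_curve(c(100, 300), c(2, 2))
  tab <- data.frame(time_s = c(0, 400), ratio = c(1, 2))
  pl <- blood_to_plasma(wb, tab)
  # at t = 100: ratio 1.25; at t = 300: ratio 1.75 (hand interpolation)
  expect_equal(pl$suv, c(2 * 1.25, 2 * 1.75))
})

test_that("the Patlak slope and intercept are exact on a synthetic linear system", {
  # constant plasma c: the anchored trapezoid gives x(T) = T - t1/2, so a
  # tissue curve linear in x recovers slope and intercept exactly
  tt <- canonical_schedule()$midpoint_s
  ki_per_s <- 0.002; v <- 0.4; cst <- 3
  plasma <- blood_curve(tt, rep(cst, 42), kind = "plasma")
  tissue <- blood_curve(tt, ki_per_s * cst * (tt - tt[1] / 2) + v * cst)
  pf <- patlak_fit(tissue, plasma, t_star = 600)
  expect_equal(pf$ki_per_min, ki_per_s * 60, tolerance = 1e-12)
  expect_equal(pf$intercept, v, tolerance = 1e-12)
  expect_equal(pf$r2, 1)
  # zero tissue gives zero influx
  zf <- patlak_fit(blood_curve(tt, rep(0, 42)), plasma)
  expect_equal(zf$ki_per_min, 0)
})

test_that("Patlak recovers the 2TCM macro influx rate within 5%", {
  kp <- kinetic_params(K1 = 0.5, k2 = 0.3, k3 = 0.1, vB = 0)
  tt <- canonical_schedule()$midpoint_s
  aif <- aif_function(aif_params())
  plasma <- blood_curve(tt, aif(tt), kind = "plasma")
  tissue <- blood_curve(tt, simulate_2tcm(kp, aif, tt))
  pf <- patlak_fit(tissue, plasma, t_star = 600)
  expect_lt(abs(pf$ki_per_min - 0.125) / 0.125, 0.05)
})

test_that("the Patlak estimate scales linearly in tissue and inversely in plasma", {
  kp <- kinetic_params(K1 = 0.4, k2 = 0.5, k3 = 0.08, vB = 0)
  tt <- canonical_schedule()$midpoint_s
  aif <- aif_function(aif_params())
  plasma <- blood_curve(tt, aif(tt), kind = "plasma")
  tissue <- blood_curve(tt, simulate_2tcm(kp, aif, tt))
  base <- patlak_fit(tissue, plasma)$ki_per_min
  up <- patlak_fit(blood_curve(tt, tissue$suv * 3), plasma)$ki_per_min
  expect_equal(up, 3 * base, tolerance = 1e-10)
  dn <- patlak_fit(tissue, blood_curve(tt, plasma$suv * 2, kind = "plasma"))$ki_per_min
  expect_equal(dn, base / 2, tolerance = 1e-10)
})

test_that("the Patlak error shrinks as t* moves into the linear phase", {
  kp <- kinetic_params(K1 = 0.5, k2 = 0.3, k3 = 0.1, vB = 0)
  tt <- canonical_schedule()$midpoint_s
  aif <- aif_function(aif_params())
  plasma <- blood_curve(tt, aif(tt), kind = "plasma")
  tissue <- blood_curve(tt, simulate_2tcm(kp, aif, tt))
  errs <- vapply(c(150, 600, 1200), function(ts)
    abs(patlak_fit(tissue, plasma, t_star = ts)$ki_per_min - 0.125), numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("voxelwise Patlak maps reproduce the single-curve fit bit for bit", {
  # an organ without a vascular fraction, so the Patlak slope targets the
  # pure tissue macro parameter K1*k3/(k2+k3)
  spec <- phantom_spec(organs = list(
    organ = list(center = c(16, 8, 8), axes = c(3, 3, 3),
                 kinetics = kinetic_params(K1 = 0.7, k2 = 1.2, k3 = 0.1, vB = 0))),
    noise_scale = 0)
  ph <- generate_phantom(spec, seed = 401)
  plasma <- blood_to_plasma(ph$aif, 1)
  mask <- ph$masks == 2L
  maps <- patlak_image(ph$image, plasma, t_star = 600, mask = mask)
  expect_equal(maps$n_failed, 0L)
  # homogeneous organ: every voxel carries the same TAC, so the map is uniform
  kis <- maps$ki[mask]
  expect_equal(max(kis) - min(kis), 0)
  # a random voxel against patlak_fit
  ix <- which(mask, arr.ind = TRUE)[5, ]
  tac <- blood_curve(ph$image$schedule$midpoint_s,
                     ph$image$values[, ix[1], ix[2], ix[3]])
  single <- patlak_fit(tac, plasma, t_star = 600)
  expect_identical(maps$ki[ix[1], ix[2], ix[3]], single$ki_per_min)
  # unmasked voxels are flagged, not computed
  expect_true(all(is.na(maps$ki[!mask])))
  # and the organ's median Ki matches its generating kinetics within 5%
  truth <- ki_macro(ph$spec$organs$organ$kinetics)
  expect_lt(abs(stats::median(kis) - truth) / truth, 0.05)
})

test_that("compartment-model fitting recovers noiseless generating parameters within 1%", {
  kp <- kinetic_params(K1 = 0.5, k2 = 0.3, k3 = 0.1, vB = 0)
  tt <- canonical_schedule()$midpoint_s
  plasma <- blood_curve(tt, aif_model(aif_params(), tt), kind = "plasma")
  tissue <- sim_grid_tissue(kp, plasma, tt)
  fit <- fit_2tcm(tissue, plasma,
                  init = kinetic_params(K1 = 0.2, k2 = 0.6, k3 = 0.03, vB = 0))
  expect_true(fit$converged)
  expect_lt(abs(fit$params$K1 - 0.5) / 0.5, 0.01)
  expect_lt(abs(fit$params$k2 - 0.3) / 0.3, 0.01)
  expect_lt(abs(fit$params$k3 - 0.1) / 0.1, 0.01)
  expect_lt(abs(fit$ki_per_min - 0.125) / 0.125, 0.01)
})

test_that("degenerate tissue and invalid starts are handled", {
  tt <- canonical_schedule()$midpoint_s
  plasma <- blood_curve(tt, aif_model(aif_params(), tt), kind = "plasma")
  zero <- blood_curve(tt, rep(0, 42))
  fit <- fit_2tcm(zero, plasma, init = kinetic_params(K1 = 0.1, k2 = 0.3, k3 = 0.02, vB = 0))
  expect_lt(fit$params$K1, 1e-6)  # driven to the lower bound
  expect_error(
    fit_2tcm(zero, plasma, init = kinetic_params(K1 = 10, k2 = 0.3, k3 = 0.02, vB = 0)),
    "outside the bounds")
})

test_that("tidy and glance methods expose fit results as tibbles", {
  tt <- canonical_schedule()$midpoint_s
  plasma <- blood_curve(tt, rep(2, 42), kind = "plasma")
  tissue <- blood_curve(tt, 0.002 * 2 * tt + 0.3 * 2)
  pf <- patlak_fit(tissue, plasma)
  expect_identical(tidy(pf)$term, c("Ki", "intercept"))
  expect_equal(glance(pf)$ki_per_min, pf$ki_per_min)
})
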