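#' Synthetic dynamic-PET phantom specification
#'
#' A phantom is a voxel grid populated with ellipsoidal "organs", each
#' carrying irreversible 2TCM kinetics driven by a shared tri-exponential
#' ground-truth input function, plus a blood-pool ellipsoid that carries the
#' input function itself.  Frame-wise Poisson count noise reproduces the
#' duration-dependent signal-to-noise of real framing: expected counts per
#' voxel are `SUV x duration x noise_scale`, so short early frames are
#' visibly noisier than the long late frames.
#'
#' The default emulates the structure of a whole-body mouse FDG study at
#' reduced resolution: the canonical 42-frame schedule, a 32 x 16 x 16 grid
#' (the full 96 x 48 x 48 geometry is a parameter, not a code path), a
#' cardiac blood pool, a myocardium-like and a brain-like organ over a
#' low-uptake background.
#'
#' @param grid_shape Integer length-3 `(depth, height, width)`.
#' @param spacing Voxel spacing in mm.
#' @param schedule A [frame_schedule()].
#' @param aif An [aif_params()] ground-truth input function.
#' @param blood_pool List with `center` and `axes` (voxel units) of the
#'   blood-pool ellipsoid.
#' @param organs Named list; each element has `center`, `axes` and
#'   `kinetics` (a [kinetic_params()]).
#' @param background [kinetic_params()] for all unassigned voxels.
#' @param body_weight_g,injected_dose_kbq Subject constants recorded with
#'   the phantom (used for SUV bookkeeping).
#' @param noise_scale Expected counts per (SUV x second); 0 means noiseless.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(32L, 16L, 16L),
                         spacing = c(0.8, 0.8, 0.8),
                         schedule = canonical_schedule(),
                         aif = aif_params(),
                         blood_pool = list(center = c(6, 8, 8), axes = c(3, 2.5, 2.5)),
                         organs = list(
                           myocardium = list(
                             center = c(16, 8, 8), axes = c(3, 3, 3),
                             kinetics = kinetic_params(K1 = 0.7, k2 = 1.2, k3 = 0.1, vB = 0.3)),
                           brain = list(
                             center = c(27, 8, 8), axes = c(3.5, 3, 3),
                             kinetics = kinetic_params(K1 = 0.25, k2 = 0.25, k3 = 0.05, vB = 0.05))),
                         background = kinetic_params(K1 = 0.1, k2 = 0.5, k3 = 0.01, vB = 0.02),
                         body_weight_g = 25,
                         injected_dose_kbq = 8000,
                         noise_scale = 5) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))
  stopifnot(inherits(schedule, "frame_schedule"), inherits(aif, "aif_params"),
            inherits(background, "kinetic_params"))
  if (noise_scale < 0) stop("`noise_scale` must be >= 0")
  check_ell <- function(e, nm) {
    if (length(e$center) != 3L || length(e$axes) != 3L || any(e$axes <= 0))
      stop("ellipsoid `", nm, "` needs 3-vector center and positive axes")
    if (any(e$center - e$axes < 0.5) || any(e$center + e$axes > grid_shape + 0.5))
      stop("ellipsoid `", nm, "` does not lie within the grid")
  }
  check_ell(blood_pool, "blood_pool")
  for (nm in names(organs)) {
    check_ell(organs[[nm]], nm)
    stopifnot(inherits(organs[[nm]]$kinetics, "kinetic_params"))
  }
  structure(list(grid_shape = grid_shape, spacing = as.numeric(spacing),
                 schedule = schedule, aif = aif, blood_pool = blood_pool,
                 organs = organs, background = background,
                 body_weight_g = body_weight_g,
                 injected_dose_kbq = injected_dose_kbq,
                 noise_scale = noise_scale),
            class = "phantom_spec")
}

ellipsoid_mask <- function(grid_shape, center, axes) {
  d <- seq_len(grid_shape[1]); h <- seq_len(grid_shape[2]); w <- seq_len(grid_shape[3])
  dd <- ((d - center[1]) / axes[1])^2
  hh <- ((h - center[2]) / axes[2])^2
  ww <- ((w - center[3]) / axes[3])^2
  outer(outer(dd, hh, `+`), ww, `+`) <= 1
}

#' Generate a synthetic dynamic PET image with known ground truth
#'
#' Voxels inside each organ carry that organ's frame-averaged 2TCM tissue
#' curve; blood-pool voxels carry the frame-averaged ground-truth input
#' function; everything else carries the background kinetics.  If
#' `noise_scale > 0`, per-voxel Poisson counts with expectation
#' `SUV x duration x noise_scale` are drawn frame-wise and rescaled back to
#' SUV, which leaves the expected value unchanged.  Output is bit-identical
#' for a fixed seed.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed; the generator state is isolated from the
#'   session RNG and the seed is recorded in the output.
#' @return A list of class `phantom` with elements `image`
#'   (a [dynamic_pet_image()]), `aif` (ground-truth [blood_curve()] at frame
#'   midpoints), `masks` (integer label array: 0 background, 1 blood pool,
#'   2... organs in list order), `labels` (names), `spec`, `seed`.
#' @export
generate_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  sched <- spec$schedule
  t_end <- schedule_end(sched)
  aif_fn <- aif_function(spec$aif)
  aif_frames <- frame_average(aif_fn, sched)

  # dense 2TCM solves, spline-interpolated, then frame-averaged
  dense_t <- seq(0, t_end, by = 1)
  organ_tac <- function(kp) {
    y <- simulate_2tcm(kp, aif_fn, dense_t, whole_blood_fn = aif_fn)
    frame_average(stats::splinefun(dense_t, y), sched)$suv
  }
  tac_bg <- organ_tac(spec$background)

  gs <- spec$grid_shape
  masks <- array(0L, gs)
  bp <- ellipsoid_mask(gs, spec$blood_pool$center, spec$blood_pool$axes)
  masks[bp] <- 1L
  labels <- c("blood_pool", names(spec$organs))
  tacs <- list(aif_frames$suv)
  lab <- 1L
  for (nm in names(spec$organs)) {
    lab <- lab + 1L
    og <- spec$organs[[nm]]
    m <- ellipsoid_mask(gs, og$center, og$axes)
    if (any(masks[m] != 0L))
      warning("organ `", nm, "` overlaps an earlier region; last writer wins")
    masks[m] <- lab
    tacs[[lab]] <- organ_tac(og$kinetics)
  }

  nf <- nrow(sched)
  values <- array(0, c(nf, gs))
  flat_masks <- as.vector(masks)
  for (t in seq_len(nf)) {
    frame <- rep(tac_bg[t], prod(gs))
    for (lab in seq_along(labels)) frame[flat_masks == lab] <- tacs[[lab]][t]
    values[t, , , ] <- frame
  }

  if (spec$noise_scale > 0) {
    values <- withr::with_seed(as.integer(seed), {
      noisy <- values
      for (t in seq_len(nf)) {
        scale <- sched$duration_s[t] * spec$noise_scale
        lam <- pmax(values[t, , , ], 0) * scale
        noisy[t, , , ] <- stats::rpois(length(lam), lam) / scale
      }
      noisy
    })
  }

  image <- dynamic_pet_image(values, sched, spec$spacing)
  structure(list(image = image, aif = aif_frames, masks = masks,
                 labels = labels, spec = spec, seed = as.integer(seed)),
            class = "phantom")
}

#' Sample a family of phantom specifications for a synthetic study
#'
#' Draws `n` phantoms around a base specification by jittering the
#' input-function parameters (amplitudes x U(0.7, 1.3), decay rates
#' x U(0.85, 1.15), arrival delay U(0, 15) s) and the organ rate constants
#' (x U(0.8, 1.2)); this is the between-subject variability the training
#' set must span.  Deterministic per seed.
#'
#' @param n Number of specifications.
#' @param base A [phantom_spec()] to perturb.
#' @param seed Integer seed.
#' @return A list of `n` [phantom_spec()] objects.
#' @export
sample_phantom_specs <- function(n, base = phantom_spec(), seed = 1L) {
  stopifnot(inherits(base, "phantom_spec"), n >= 1)
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      a <- base$aif
      aif <- aif_params(
        A1 = a$A1 * stats::runif(1, 0.7, 1.3),
        A2 = a$A2 * stats::runif(1, 0.7, 1.3),
        A3 = a$A3 * stats::runif(1, 0.7, 1.3),
        lambda1 = a$lambda1 * stats::runif(1, 0.85, 1.15),
        lambda2 = a$lambda2 * stats::runif(1, 0.85, 1.15),
        lambda3 = a$lambda3 * stats::runif(1, 0.85, 1.15),
        t0 = stats::runif(1, 0, 15))
      jit <- function(kp) kinetic_params(
        K1 = kp$K1 * stats::runif(1, 0.8, 1.2),
        k2 = kp$k2 * stats::runif(1, 0.8, 1.2),
        k3 = kp$k3 * stats::runif(1, 0.8, 1.2),
        vB = kp$vB)
      organs <- lapply(base$organs, function(o) {
        o$kinetics <- jit(o$kinetics); o
      })
      sp <- base
      sp$aif <- aif
      sp$organs <- organs
      sp$background <- jit(base$background)
      sp
    })
  })
}

#' Write a generated phantom to disk
#'
#' Writes the dynamic image + timing sidecar, the ground-truth input
#' function CSV, and the integer organ-label volume.
#'
#' @param phantom A `phantom` from [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dynamic_pet(phantom$image,
                    file.path(dir, "dynamic.nii.gz"),
                    file.path(dir, "timing.csv"))
  write_blood_curve(phantom$aif, file.path(dir, "aif_truth.csv"))
  write_label_volume(phantom$masks, file.path(dir, "masks.nii.gz"),
                     phantom$image$spacing)
  invisible(dir)
}

#' Read / write a phantom specification as YAML
#'
#' @param spec A [phantom_spec()].
#' @param path YAML file path.
#' @return `read_phantom_spec()` returns a [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  grp <- regroup_schedule(spec$schedule)
  x <- list(
    grid_shape = as.integer(spec$grid_shape),
    spacing = spec$spacing,
    schedule = list(group_counts = as.integer(grp$group_counts),
                    group_durations = grp$group_durations),
    aif = unclass(spec$aif),
    blood_pool = spec$blood_pool,
    organs = lapply(spec$organs, function(o)
      list(center = o$center, axes = o$axes, kinetics = unclass(o$kinetics))),
    background = unclass(spec$background),
    body_weight_g = spec$body_weight_g,
    injected_dose_kbq = spec$injected_dose_kbq,
    noise_scale = spec$noise_scale)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  phantom_spec(
    grid_shape = x$grid_shape,
    spacing = x$spacing,
    schedule = build_schedule(x$schedule$group_counts, x$schedule$group_durations),
    aif = do.call(aif_params, x$aif),
    blood_pool = x$blood_pool,
    organs = lapply(x$organs, function(o)
      list(center = o$center, axes = o$axes,
           kinetics = do.call(kinetic_params, o$kinetics))),
    background = do.call(kinetic_params, x$background),
    body_weight_g = x$body_weight_g,
    injected_dose_kbq = x$injected_dose_kbq,
    noise_scale = x$noise_scale)
}
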