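---
title: "Deep-learned input functions for dynamic small-animal PET: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep-learned input functions for dynamic small-animal PET: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Kinetic modeling of dynamic PET requires the arterial input function (AIF):
the tracer concentration in arterial blood over the course of the scan.  The
gold standard, arterial blood sampling, is terminal in mice, which rules out
longitudinal designs and caps throughput.  This package implements a fully
convolutional predictor that maps a reconstructed 4D dynamic PET volume
directly to an input-function estimate (a DLIF), plus everything needed to
exercise that claim end to end without animal data: a phantom simulator with
known ground truth, the training machinery, downstream Patlak and
compartment-model quantification, and the comparison/robustness diagnostics.

## The network

The predictor factorises into two convolutional stages.

**Spatial feature extractor (SFE).**  Each time frame (one 3D volume) is
processed independently by a small residual network whose weights are shared
across frames: an input 2x2x2 max-pool, then three residual blocks — two
same-padded 3x3x3 convolutions plus a (projected) identity skip, ReLU
activations — with max-pools after the first two blocks, a final valid
convolution with a 4x2x2 cuboid kernel, and adaptive average pooling down to
one spatial cell.  Every frame thus becomes a 32-dimensional feature vector.
Weight sharing across time means the temporal head can never key on
"frame 7 looks like this"; it must read tracer dynamics out of the feature
sequence itself, which is what makes the model robust to shifted and
truncated protocols.

**Temporal feature extractor (TFE).**  The T x 32 feature sequence is run
through three 1D convolutions (kernel width 5, zero "same" padding, channels
32 → 41 → 222 → 1; ReLU between layers, linear output).  Because every
temporal operation preserves length, the output curve has exactly as many
samples as the input has frames, for any T ≥ 1 — the network is agnostic to
the framing scheme.  The TFE receptive radius is (3 layers) x (2 frames per
side) = 6 frames; time-shift covariance holds exactly beyond that boundary,
and the test suite asserts this on an untrained seeded network.

**Where the widths come from.**  The architecture skeleton fixes everything
except the channel widths, and the published budget of exactly 90124
trainable parameters constrains but does not uniquely determine them.  The
shipped configuration — block widths (12, 4, 24), TFE 32-41-222-1 — is one
admissible member of that family, found by the enumeration in
`tools/width_search.R` and frozen.  The second block is deliberately the
narrowest: early blocks run at the highest spatial resolution, and temporal
modeling is deferred entirely to the TFE, so spending channels there buys
little.  Choices the architecture description leaves open were resolved to
the simplest ResNet-consistent option and recorded in `network_config()`:
ReLU activations, no normalization layers (training uses batch size 1, where
batch statistics are ill-defined), no dropout, no dilation.

At 90124 parameters x 4 bytes the model weighs about 352 KB in FP32 —
roughly 100x smaller than the 42 x 96 x 48 x 48 scan it consumes (about
37 MB in FP32).

The convolution engine itself (forward and backward passes, ADAM) is
implemented in this package with RcppArmadillo.  Same-padded convolutions
are evaluated by a shift decomposition on the zero-padded grid — one
accumulated GEMM per kernel tap — which is what makes CPU training of the
reduced configuration practical; gradients are verified against numerical
differentiation in the test suite.

## Training

The loss is a segment-weighted MSE over the predicted curve.  On the
canonical 42-frame schedule (1x30 s, 24x5 s, 9x20 s, 8x300 s; 2730 s total)
the first 25 frames (peak), middle 9 (intermediate) and last 8 (tail) carry
weights 0.4, 0.7 and 1.0 — roughly inverse to sampling density, so the
densely sampled bolus phase does not dominate.  Two conventions the loss
definition leaves open are fixed as: the weighted squared errors are
*averaged* over frames (keeps magnitudes comparable across sequence
lengths), and for non-canonical lengths frames are assigned to segments by
the canonical split's time boundaries (peak < 150 s ≤ intermediate < 330 s ≤
tail).

Optimization is ADAM at learning rate 1e-4 with standard moments
(0.9/0.999), batch size 1, 1000 epochs at full scale.  Data augmentation
injects additive Poisson count noise: one scalar `p ~ Unif(0,1)` per image
per epoch, then `I + Pois(I·p) − I·p` voxelwise, which preserves the
expected image exactly while sweeping the signal-to-noise ratio.  The
augmentation is applied to every sample every epoch when enabled (an
every-epoch flag is provided since the protocol leaves the cadence open).
Ten-fold cross validation with ten repeated runs per fold is supported
through `make_folds()` and seeds; the package does not attempt to reproduce
that compute at full scale.

## The phantom generator

`generate_phantom()` builds the study conditions the package is tested
under; its defaults are deliberate and not tuning knobs.

* **Geometry.**  42-frame canonical schedule; a reduced 32 x 16 x 16 grid by
  default so a full training study runs in minutes on one CPU core (the
  canonical 96 x 48 x 48 geometry is a parameter, not a code path).
  Ellipsoidal regions only: a cardiac blood pool, a myocardium-like organ
  (K1 = 0.7, k2 = 1.2, k3 = 0.1 /min, vB = 0.3), a brain-like organ
  (0.25, 0.25, 0.05, vB = 0.05) over a low-uptake background — magnitudes in
  the range reported for mouse FDG kinetics.
* **Ground truth.**  The AIF follows the classic tri-exponential bolus form
  (Feng-type), the standard parametric family for FDG input functions; the
  defaults give a sharp peak of ~7 SUV near 15 s and a slow tail of ~0.3 SUV
  at scan end, shapes typical of mouse FDG studies.  Organ curves solve the
  irreversible two-tissue compartment model driven by that AIF, and voxels
  carry the frame-averaged curves, so the blood-pool mean reproduces the
  ground-truth curve exactly in the noiseless setting.
* **Noise.**  Poisson counts with expectation SUV x frame duration x
  `noise_scale` (default 5 counts per SUV-second), rescaled back to SUV.
  Applying noise on simulated counts rather than on SUV directly reproduces
  the duration dependence of real framing — 5-s frames are visibly noisier
  than 300-s frames, which the tests assert via the coefficient of
  variation.  No quantitative scanner noise level is available to calibrate
  against, so the default is a qualitative choice, documented as such.
* **Between-subject variability.**  `sample_phantom_specs()` jitters AIF
  amplitudes (±30%), decay rates (±15%), arrival delay (0–15 s) and organ
  rate constants (±20%) — enough spread that a trained network must infer
  the curve rather than memorise it.

What the phantoms do *not* emulate: anatomical realism, scanner point-spread
and scatter, motion, attenuation artefacts.  A passing recovery study
therefore demonstrates that the architecture, loss and optimizer can extract
an input function whose information is present in the image; it does not
certify performance on any real scanner or tracer.

## The desk-scale recovery study

`aif_recovery_study()` is the package's stand-in for cross-validated
performance on real data: 20 training and 5 held-out noiseless phantoms,
reduced geometry, 80 epochs at learning rate 1e-3 without augmentation
(the noiseless protocol has nothing to denoise), seeded end to end.  The
elevated learning rate and short schedule are the appropriate scale for this
small, clean task; the full-scale defaults in `train_config()` are
unchanged.  The study requires held-out Pearson r ≥ 0.95; in practice it
reaches r > 0.999.  Runtime is roughly 8 minutes on one CPU core, the
problem size stated throughout the tests and acceptance script.

## Downstream quantification

**Plasma conversion.**  Kinetic models are driven by plasma concentration.
`blood_to_plasma()` takes a pluggable ratio model — a constant or a
time-tabulated ratio, linearly interpolated — because no specific
whole-blood-to-plasma relationship is bundled; the default ratio of 1.0 is a
placeholder and real studies must supply a tracer-specific model.

**Patlak.**  `patlak_fit()` regresses normalized uptake
\(C_t(T)/C_p(T)\) on normalized integrated input
\(\int_0^T C_p\,dt / C_p(T)\) over frames with midpoints ≥ `t_star`; the
slope is the net influx rate Ki (reported per minute).  Numerical
conventions: the running integral is trapezoidal with the curve anchored at
(0, 0) — tracer concentration is zero at injection; `t_star` defaults to
600 s, the onset of the 300-s frames, safely past the distribution phase the
Patlak model discards.  For an irreversible 2TCM tissue the slope converges
to \(K_1 k_3/(k_2+k_3)\), and the tests assert monotone error decay in
`t_star` plus recovery within 5% at the default.  The intercept is reported
as "intercept" without further physiological interpretation.  Voxelwise maps
(`patlak_image()`) reuse the identical arithmetic per voxel — a masked voxel
reproduces the single-curve fit bit for bit — and flag failed voxels rather
than aborting the map.

**Compartment fitting.**  `fit_2tcm()` does bounded Levenberg-Marquardt
least squares of the irreversible 2TCM forward model (uniform residual
weights by default; the weighting convention is otherwise open).  The
forward model inside the optimizer integrates the linear system on a fixed
0.5-s grid with an exponential-trapezoid recursion rather than an adaptive
ODE solver: adaptive step-size control makes the objective non-smooth at
finite-difference scale and silently stalls the fit, while the fixed-grid
scheme agrees with the reference solver `simulate_2tcm()` (deSolve) to below
1e-4 relative and leaves the Jacobian clean.  Noiseless round trips recover
the generating parameters essentially exactly.

## Evaluation and robustness

`compare_curves()` reports the unweighted MSE, per-frame differences with
segment labels, Pearson r, r² (the squared correlation — identical about any
fitted straight line, orthogonal or ordinary, so the ambiguity costs
nothing), a Deming regression line, a paired t-test across frames at
α = 0.05, and sorted quantile-quantile pairs for normality inspection
(emitted, not interpreted).  `frame_ttests()` runs the per-frame paired
tests across a dataset, unadjusted by default with a Bonferroni option.
Orthogonal regression uses the closed-form Deming estimator with variance
ratio 1 (exposed as a parameter); the ratio-1 fit is swap-symmetric and the
infinite-ratio limit reproduces ordinary least squares, both asserted in
tests.

The robustness operations mirror the two protocol perturbations of
interest: `shift_test()` prepends one 30-s frame (all-zero by default — the
two natural readings of "prepend the initial frame" are both implemented,
`mode = "empty"` and `mode = "copy"`) and scores alignment of the shifted
prediction against the original; `truncate_test()` drops the first 4 and
last 6 frames.  On the canonical schedule the four dropped head frames span
45 s (30 + 3x5) even though the protocol is colloquially described as
dropping "the first 40 s"; the schedule arithmetic is treated as
authoritative and the label as approximate.  `tsne_features()` embeds SFE
feature vectors in 2D with an exact O(N²) t-SNE (implemented here,
deterministic per seed — adequate for the few hundred frame vectors a study
produces) and attaches peak/intermediate/tail and group labels.

## Known limitations

* The spatial input shape is fixed per trained network; only the temporal
  dimension is free.  Data from other geometries must be resampled.
* The phantom family is geometrically and physically idealised (see above);
  transfer claims to real tracers or scanners are out of scope, as is any
  reproduction of the published animal-data scores.
* Only the irreversible (k4 = 0) compartment model is implemented.
* The exact t-SNE is quadratic in the number of frame vectors; it is a
  diagnostic, not a pipeline stage.
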