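# fcdlif

Non-invasive estimation of the arterial input function (AIF) from dynamic
small-animal PET, for preclinical imaging groups doing kinetic modeling in
mice.  Arterial blood sampling — the gold standard for the AIF — is a
terminal procedure in mice, blocking longitudinal studies.  `fcdlif`
implements a fully convolutional deep model that predicts the input
function directly from the reconstructed 4D scan, together with the
training machinery, a synthetic phantom generator with known ground truth,
downstream kinetic quantification, and the evaluation/robustness suite.

## The model

A **spatial feature extractor** (a compact 3D residual network, weights
shared across time) maps each time frame to a 32-dimensional feature
vector; a **temporal feature extractor** (1D convolutions with "same"
padding, channels 32 → 41 → 222 → 1) turns the feature sequence into the
predicted curve.  All operations preserve temporal length, so a scan with
any number of frames T yields a T-point input function — the model has no
fixed-length layers to break on shifted or truncated protocols.  The
default configuration carries exactly **90 124 trainable parameters**
(~352 KB in FP32, versus ~37 MB for one 42×96×48×48 scan).

Training minimises a segment-weighted MSE over the curve — peak /
intermediate / tail frames (25/9/8 of the canonical 42-frame schedule)
weighted 0.4 / 0.7 / 1.0 — with ADAM and additive Poisson count-noise
augmentation `I + Pois(I·p) − I·p`, `p ~ Unif(0,1)` per image per epoch.

Downstream, Patlak graphical analysis estimates the net influx rate
`Ki = K1·k3/(k2+k3)` (per minute) from the predicted input function, and a
bounded Levenberg–Marquardt fitter recovers irreversible two-tissue
compartment (2TCM) rate constants.

There is no deep-learning framework underneath: the convolution engine
(forward, backward, ADAM) is part of the package, written with
RcppArmadillo and verified by numerical gradient checks.

## Worked example

```r
library(fcdlif)

# the shipped architecture
net <- build_network(network_config(), seed = 1)
count_parameters(net)
#> [1] 90124

# a synthetic mouse-like phantom with known ground-truth input function
ph <- generate_phantom(phantom_spec(noise_scale = 0), seed = 1)
ph$image
#> <dynamic_pet_image> 42 frames x 32 x 16 x 16 voxels, 2730 s total
#>   spacing 0.80 x 0.80 x 0.80 mm, SUV range [0.113, 7.29]
head(ph$aif, 3)
#> # A tibble: 3 x 2
#>   time_s   suv
#>    <dbl> <dbl>
#> 1   15    7.29   # bolus peak in the first frame
#> 2   32.5  6.69
#> 3   37.5  5.28

# Patlak quantification of a simulated irreversible 2TCM tissue
kp <- kinetic_params(K1 = 0.5, k2 = 0.3, k3 = 0.1, vB = 0)
tissue <- blood_curve(ph$aif$time_s,
                      simulate_2tcm(kp, aif_function(ph$spec$aif), ph$aif$time_s))
plasma <- blood_to_plasma(ph$aif, ratio = 1)
patlak_fit(tissue, plasma, t_star = 600)
#> <patlak_fit> Ki = 0.12669 /min, intercept = 1.208, r2 = 1.0000 (7 frames, t* = 600 s)
```

The fitted `Ki = 0.127/min` sits within 1.4% of the closed-form macro
parameter `K1·k3/(k2+k3) = 0.125/min`, showing the graphical estimate
agreeing with the generating kinetics once the linear phase is reached.

Training end to end on phantoms:

```r
study <- aif_recovery_study(n_train = 20, n_test = 5, epochs = 80,
                            learning_rate = 1e-3, seed = 1)
min(study$heldout_r)   # Pearson r vs ground truth on held-out phantoms, > 0.99
```

A command-line wrapper (`inst/exec/fcdlif`) exposes `simulate`, `train`,
`predict`, `evaluate`, `patlak`, `robustness`, `features` and `describe`
subcommands; every run writes a manifest (arguments, seed, version) next to
its outputs.

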