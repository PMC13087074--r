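Package: fcdlif
Title: Fully Convolutional Deep-Learned Input Functions for Dynamic Small-Animal PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-invasive estimation of the arterial input function (AIF)
    directly from 4D dynamic PET volumes with a compact fully convolutional
    network: a weight-shared 3D spatial feature extractor applied to every
    time frame, followed by a 1D temporal convolutional head that emits an
    input-function value per frame, so any number of frames is accepted.
    Includes the weighted-MSE training loop with Poisson count-noise
    augmentation and k-fold cross validation, a synthetic dynamic-PET
    phantom generator with known ground-truth input functions and
    irreversible two-tissue-compartment organ kinetics, downstream Patlak
    net-influx mapping and compartment-model fitting, and a suite of
    comparison and robustness diagnostics (orthogonal regression,
    time-shift and truncation tests, t-SNE exploration of frame features).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    deSolve,
    minpack.lm,
    pracma,
    tibble,
    dplyr,
    tidyr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
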