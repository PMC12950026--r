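Package: hairplate
Title: Spiking Neural Network Encoding of Joint Kinematics by Proprioceptive Hair Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates range-fractionated proprioceptive hair-field arrays of
    insect legs as a two-layer spiking neural network. Joint-angle time series
    are converted to per-hair deflections by overlapping receptive fields,
    encoded by adaptive exponential integrate-and-fire (AdEx) mechanosensory
    afferents with phasic-tonic dynamics, and decoded by leaky integrate-and-fire
    (LIF) position interneurons and high-pass LIF velocity chains. Includes
    ramp-and-hold and constant-velocity stimulus protocols, a synthetic gait
    generator, rate estimation, z-normalised MSE / MAE / confusion-matrix
    evaluation metrics, lag correction, and the calibration grid searches for
    the afferent and position-decoder parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
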