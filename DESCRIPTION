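Package: sawoce
Title: Depth-Resolved Surface Acoustic Wave Phase Velocity Estimation for
    Optical Coherence Elastography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for depth-resolved phase velocity estimation in surface
    acoustic wave optical coherence elastography (SAW-OCE). Provides a
    physics-based numerical spectral analysis (NSA) estimator that converts
    depth-resolved lateral-temporal phase images into frequency-wavenumber
    energy maps and extracts phase velocity by a weighted spectral centroid;
    robust LOESS profile smoothing and bilinear (piecewise-linear) interface
    detection with a free velocity jump; a synthetic SAW-OCE volume simulator
    with known layered ground truth; and PVNet, a hybrid convolutional /
    efficient-additive-attention regression network with rotary positional
    embeddings, implemented natively with hand-derived gradients and trained
    at desk scale on simulated phase images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rhdf5,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
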