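Package: bcgbp
Title: Cuffless Blood Pressure Estimation from Two-Channel Ballistocardiograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end pipeline for estimating systolic and diastolic blood
    pressure from a two-channel chair ballistocardiogram (BCG): Butterworth
    band-pass isolation of the cardiac band, empirical mode decomposition by
    envelope-mean sifting, Hilbert-transform instantaneous phase of the first
    intrinsic mode function, a 1-D convolutional neural network regressor
    trained with 10-fold cross-validation, and AAMI-style agreement evaluation
    (mean error, error standard deviation, Bland-Altman limits of agreement).
    Includes a seeded synthetic two-channel BCG generator that encodes blood
    pressure in the inter-channel beat transit delay, so the full pipeline can
    be exercised and validated without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
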