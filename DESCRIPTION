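Package: hotspotEEG
Title: EEG-Based Motor Hotspot Localization with a Convolutional Neural
    Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Localizes the hand-muscle motor hotspot from movement-related
    EEG by regressing its 3D coordinates (mm, vertex origin) with a deep 2D
    convolutional network. Provides 10-20 electrode montage geometry and
    channel-set selection, EDF and plain-matrix recording I/O, a seeded
    synthetic movement-EEG simulator with known ground-truth hotspots, the
    five-level preprocessing ladder (downsampling, common average
    reference, zero-phase Butterworth band-pass, ICA artifact removal,
    epoching, gamma-band power spectral densities), nested 5x5-fold
    cross-validation with early stopping, Euclidean error-distance scoring,
    channel and trial ablations, and Friedman/Wilcoxon comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
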