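Package: lutomo
Title: Laser-Ultrasound Time-of-Flight Tomography of Tissue Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for through-transmission
    laser-ultrasound speed-of-sound (SoS) tomography of tissue-mimicking
    phantoms. Generates randomised circular gel phantoms with fluid
    inclusions, computes first-arrival travel-time fields through the
    resulting SoS maps with an isotropic fast-marching eikonal solver
    refined by bent-ray tracing, assembles two-view generation-by-detection
    time-of-flight (ToF) matrices, synthesises broadband A-scans, picks
    pulse onsets with a two-stage kurtosis plus cross-correlation method,
    reconstructs class-coded SoS maps from stacked ToF inputs with a
    convolutional encoder-decoder trained on simulated data, and quantifies
    reconstructions via diameter and centre-offset metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    tiff,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
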