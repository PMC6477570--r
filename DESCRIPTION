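Package: pulseTherm
Title: Instant Perceived-Stress Detection from Smartphone PPG and Nose-Tip Thermal Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for instant (20-second) perceived-stress measurement from
    two smartphone-based cardiovascular channels. Blood-volume-pulse signals
    are extracted from finger-on-camera R-channel frame stacks via the
    negative temporal variation of spatial Shannon entropy, upsampled,
    amplitude-equalized and peak-picked into pulse-to-pulse (PP) intervals.
    Nose-tip temperature sequences are cleaned of respiratory oscillation by
    zero-phase low-pass filtering and turned into 1 Hz min-max-scaled thermal
    variability sequences. The package computes power signal quality indices
    (pSQI), pulse-rate-variability and thermal features, normalizes and
    clusters visual-analog-scale stress self-reports into binary labels, and
    evaluates single-hidden-layer neural networks and 1-nearest-neighbour
    classifiers under leave-one-subject-out cross-validation. A synthetic-data
    generator produces pulse-modulated frame stacks, breathing-contaminated
    thermal series and multi-participant scored cohorts with planted stress
    effects, so the full pipeline is testable without any recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    png,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
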