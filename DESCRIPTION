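Package: blinkMux
Title: Blink-Based Multiplexing of Single-Molecule Emitters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of single-molecule fluorescence blinking for blink-based
    multiplexing (BBM): simulation of binned emission-time traces under
    mechanistic on/off duration models (dispersive electron transfer, ESIPT,
    quantum-dot power-law kinetics), generalized likelihood-ratio change-point
    detection on Poisson photon counts, intensity-level grouping and on/off
    labelling, extraction of the ten per-molecule blinking statistics,
    maximum-likelihood fitting of heavy-tailed event-duration distributions
    with Kolmogorov-Smirnov goodness of fit, and multinomial logistic
    classification with probability thresholding and data-retention analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nnet,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'blinkMux-package.R'
    'blinkstats.R'
    'changepoint.R'
    'classifier.R'
    'durationfit.R'
    'io.R'
    'pipeline.R'
    'simulate.R'
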