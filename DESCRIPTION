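Package: procspec
Title: In-Line NIR Moisture Monitoring of Fluidized-Bed Drying by
    Time-Domain Spectral Smoothing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chemometric toolkit for in-line near-infrared moisture
    monitoring of fluidized-bed drying processes. Implements moving-window
    smoothing of spectral variables along the time domain as an
    information-preserving alternative to scatter correction, conventional
    scatter-corrective preprocessing (multiplicative scatter correction,
    standard normal variate, Savitzky-Golay derivatives) for comparison,
    exploratory wavelength-wise correlation and principal component
    analysis of augmented batch trajectories, NIPALS partial least-squares
    calibration with leave-one-out, leave-a-batch-out and external
    validation, window-width and moisture-range model optimization, a
    dynamic model-focusing streaming predictor, and a synthetic drying
    campaign simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'classes-dataset.R'
    'io.R'
    'simulate.R'
    'dataset-ops.R'
    'preprocess.R'
    'pls.R'
    'validate.R'
    'strategy.R'
    'cli.R'
    'explore.R'
    'procspec-package.R'
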