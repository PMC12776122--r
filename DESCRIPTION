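Package: aperiodics
Title: Time-Resolved Aperiodic (1/f) Spectral Slope Analysis of Task EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the instantaneous aperiodic (1/f) spectral slope of
    stimulus-locked EEG epochs with single-cycle wavelet pairs and tracks its
    modulation by congruency and congruency-sequence manipulations. Provides a
    synthetic EEG and behavior generator with programmable ground-truth
    exponent dynamics, trial-exclusion and artifact-rejection rules, ERP
    subtraction, spatial and temporal PCA with Empirical Kaiser Criterion
    retention and varimax rotation, FWHM-based time-window segmentation, and
    within-subject ANOVA tables with follow-up paired contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllGenerics.R'
    'AllClasses.R'
    'aperiodics-package.R'
    'utils.R'
    'stats.R'
    'behavior.R'
    'preprocess.R'
    'slope.R'
    'reduce.R'
    'pipeline.R'
    'io.R'
    'layout.R'
    'synth-signal.R'
    'synth-dataset.R'
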