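Package: eegdeficits
Title: Quantitative EEG Deficit Profiling for Two-Group Cohort Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for detecting group-level neurophysiological
    deficits from multi-channel resting-state EEG. Implements band-pass
    conditioning, state-transition trimming, one-second epoching and
    iterative high-power epoch rejection; FFT power spectral density at
    1-Hz-bin and conventional-band resolution with average-then-log
    aggregation; Hjorth time-domain parameters, approximate entropy and the
    rescaled-range Hurst exponent at broadband, band and single-frequency
    scope; and normality-gated two-group testing with optional Bonferroni
    adjustment and contiguous significant-frequency-range summaries. A
    synthetic cohort generator based on exact fractional Gaussian noise with
    spectrum shaping provides ground-truth test beds for calibration and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'eegdeficits-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'config.R'
    'spectral.R'
    'features.R'
    'io.R'
    'methods.R'
    'preprocess.R'
    'stats.R'
    'pipeline.R'
    'plot.R'
    'synth.R'
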