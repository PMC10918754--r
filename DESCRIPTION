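Package: boldvar
Title: BOLD Signal Variability and Executive Functions Across the Life Span
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes moment-to-moment BOLD signal variability (root mean
    squared successive differences, rMSSD) from parcellated resting-state
    fMRI time series, with a whole-brain successive-difference regression
    adjustment that orthogonalizes network-specific from global variability.
    Fits a correlated four-factor confirmatory factor model of executive
    functions by maximum likelihood (fit indices, modification of residual
    covariances, regression-method factor scores) and relates the resulting
    factor scores to network variability through age-moderated regressions
    with FDR correction, simple slopes, and polynomial age curves. Includes a
    synthetic-cohort generator with known ground truth emulating a life-span
    resting-state study, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
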