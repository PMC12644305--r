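Package: hdps
Title: High-Dimensional Propensity Score Weighting for Active-Comparator
    Cohort Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for confounding adjustment in electronic-health-record
    cohort studies using high-dimensional propensity scores (HDPS).
    Implements mapping of raw clinical, prescription and hospital codes to
    harmonized vocabularies, construction of binary recurrence covariates
    (once / sporadic / frequent), prioritisation of candidate covariates by
    the Bross bias formula with instrument-exclusion cutoffs, stabilized
    inverse-probability-of-treatment weighting with common-support trimming,
    weighted Cox, logistic and risk-difference outcome models with robust
    variances, covariate balance diagnostics, and one-by-one covariate
    sensitivity analyses.  A synthetic cohort generator with latent
    severity and frailty emitting proxy codes across care dimensions
    supports end-to-end validation without access to confidential data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    sandwich,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
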