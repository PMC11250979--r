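Package: collideripw
Title: Collider Bias Correction for Hospitalised Cohorts via Externally
    Derived Inverse Probability of Selection Weights
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for correcting collider (selection) bias in hospitalised
    cohort studies using only external summary data. Fits a saturated
    log-link model for the probability of hospitalisation given exposure
    (ethnic group), outcome (death) and epidemic wave from published
    stratum counts, inverts the predicted probabilities into inverse
    probability of selection weights, and applies them in weighted
    cause-specific Cox proportional hazards models for death with
    discharge as a competing event and robust standard errors. Includes a
    structured misspecification sensitivity grid for the selection-model
    coefficients and a synthetic population generator that reproduces the
    collider structure (exposure and outcome both raising the probability
    of hospitalisation) so the full pipeline is testable without access to
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
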