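Package: tsbdecay
Title: Patient-Specific Exponential Decay Modelling of Serum Bilirubin in
    Very Preterm Infants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the postnatal decline of total serum
    bilirubin (TSB) in very preterm infants (24-32 weeks of gestation).
    Provides a patient-specific, gestational-age-shifted exponential decay
    model fitted by bounded robust nonlinear least squares with multi-start
    and an adaptive robustness strategy, cohort inclusion/exclusion filtering
    (minimum sample counts, monitoring gaps, removal of samples drawn during
    phototherapy or exchange transfusion), population-level parameter
    summaries with a median model and local one-at-a-time sensitivity
    analysis, and residual-based association of model misfit with elevated
    C-reactive protein and clinical events. Includes a synthetic cohort
    generator with ground truth for recovery and detection experiments,
    CSV input/output with validation, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
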