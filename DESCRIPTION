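Package: sraroc
Title: Diagnostic Thresholds for the Sural/Radial Amplitude Ratio via
    Binormal ROC Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Evaluates the sural/radial sensory nerve action potential
    amplitude ratio (SRAR) as a discriminator between non-length-dependent
    (sensory neuronopathy, CIDP) and length-dependent polyneuropathies.
    Computes patient-level SRAR from electrodiagnostic records using the
    lower-of-sides and first-study rules, fits a parametric binormal ROC
    model after log transformation, selects decision-theoretic optimal
    thresholds driven by pre-test probability and a risk cut-off
    preference, quantifies uncertainty with the percentile bootstrap, and
    reports prevalence-adjusted predictive values. Includes a synthetic
    cohort generator calibrated by median/IQR moment matching for
    end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), pROC, jsonlite, yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
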