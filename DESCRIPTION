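Package: screenval
Title: Diagnostic Accuracy of Multi-Informant Screening Items and
    Prevalence Projection from Positive Predictive Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates brief multi-informant screening questionnaires
    (parent and self report) against a clinician reference standard under
    skip-rule verification routing, as used in the DAWBA-based national
    mental-health surveys of children and young people. Scores five-item
    screens at configurable thresholds, builds 2x2 confusion tables,
    computes sensitivity, specificity, predictive values and accuracy with
    Wald or exact (Clopper-Pearson) confidence intervals, recomputes
    accuracy under an assumed false-negative rate among screen-negatives,
    back-solves integer confusion-table cells from published rounded
    metrics, projects population prevalence onto a later survey wave by
    multiplying screen-positive proportions by positive predictive values,
    and generates synthetic survey microdata with the same dyad and
    routing structure for testing without restricted data.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
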