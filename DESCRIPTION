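Package: ckdcodes
Title: Validation of Administrative Code Algorithms for Chronic Kidney Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating administrative-database diagnosis-code
    algorithms for chronic kidney disease against a serum-creatinine /
    estimated-GFR reference standard. Provides a synthetic claims-cohort
    simulator with known ground truth, cohort accrual at an index outpatient
    prescription with inclusion and exclusion rules, CKD-EPI eGFR estimation
    and threshold classification, code-list algorithm construction and
    evaluation over a look-back window, and diagnostic-accuracy statistics
    (sensitivity, specificity, predictive values) with Wilson score
    confidence intervals, stratified by age, sex, and eGFR threshold.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    lubridate,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
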