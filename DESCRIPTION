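Package: pnigars
Title: Rule-Based Grading of Pulmonary Nodules with PNI-GARS and Lung-RADS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic rule engines for two CT pulmonary-nodule
    classification systems: the Pulmonary Node Imaging-Grading And
    Reporting System (PNI-GARS, grades 0 to IV) and the American College
    of Radiology Lung-RADS 2022 categories (1 to 4X). Includes screen
    dichotomization, stratified diagnostic-accuracy summaries (sensitivity,
    specificity, agreement rate with Wald confidence intervals), a
    chi-square/Fisher/McNemar testing toolkit with an expected-frequency
    driven test-selection rule, seeded synthetic-cohort generation, and a
    deterministic reconstructor for a 7,781-nodule benchmark cohort whose
    per-stratum confusion tables are fixed by design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
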