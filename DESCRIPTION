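Package: rxlines
Title: Line-of-Therapy Assignment and Prescribing Variation Analysis for
    Antidiabetic Drugs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for drug-utilization research on non-insulin antidiabetic
    prescribing. Classifies drugs into the six antidiabetic classes with
    dataset-specific combination-product handling, ascertains a type 2
    diabetes cohort from longitudinal primary-care event tables, assigns
    first- to fourth-line therapy from first-ever class starts with
    gap-based treatment episodes, normalises national dispensing tables to
    inflation-corrected per-patient rates, summarises geographic variation
    in class mix and spend across commissioning groups with decile time
    series and a lowest-decile potential-savings estimator, and generates
    synthetic patient-level and practice-level datasets with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
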