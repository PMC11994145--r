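Package: lacescore
Title: LACE Index Readmission Risk Scoring with Dictionary-Based Comorbidity Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for 30-day unplanned hospital readmission risk analysis with
    the LACE index (Length of stay, Acuity of admission, Comorbidity, Emergency
    department visits). Computes Charlson comorbidity scores from free-text
    patient histories via a weighted keyword dictionary, assembles LACE
    component points and the 0-19 total with a configurable high-risk
    threshold, evaluates the flag against unplanned readmission (sensitivity,
    specificity, predictive values, accuracy with exact binomial intervals,
    no-information rate), compares readmission groups (Welch t, Yates-corrected
    chi-square), and fits logistic readmission models reporting odds ratios
    with Wald intervals. Includes a seeded synthetic cohort generator with
    planted dictionary terms and known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
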