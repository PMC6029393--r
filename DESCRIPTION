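Package: methpanel
Title: Diagnostic Evaluation of Urine DNA Methylation Marker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for multi-marker methylation-specific qPCR
    (MS-qPCR) diagnostic panels assayed in urine DNA, built around a
    19-CpG-island / 24-assay prostate-cancer panel. Converts quantification
    cycle (Cq) tables to transformed methylation levels, merges dual assays
    per CpG island, computes the number-of-positive-markers and
    average-methylation scores, evaluates diagnostic operating
    characteristics (sensitivity, specificity, predictive values with
    configurable confidence intervals), enumerates AUCs over all small marker
    subsets, performs paired comparisons of two urine collection methods
    (post-digital-rectal-exam versus first void), and generates calibrated
    synthetic cohorts for testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
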