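Package: pp13screen
Title: MoM Normalization, ABO Blood-Group Adjustment and Screening
    Evaluation for Maternal Serum PP13
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for first-trimester serum biomarker screening analysis
    built around placental protein 13 (PP13, galectin-13): conversion of
    concentrations to gestational-week-specific multiples of the median
    (MoM), sequential covariate adjustment (BMI, ethnicity, smoking,
    maternal age, parity), ABO blood-group adjustment, leave-one-out
    out-of-sample risk scoring, ROC and likelihood-ratio evaluation at
    fixed false-positive rates for preeclampsia and intrauterine growth
    restriction, and a synthetic longitudinal cohort generator with the
    statistical structure these analyses assume. Also summarizes
    erythrocyte-binding panels and quantifies the inverse-mirror relation
    between red-cell binding and serum level across blood groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
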