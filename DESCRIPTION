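Package: dascreen
Title: Validation Pipeline for a Brief Adolescent Dating-Abuse Screener
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to validate a three-item adolescent dating-abuse
    victimization screener against a 34-item reference instrument:
    instrument scoring and screener-item selection, record quality-control
    and survey-fraud filtering with a stage-by-stage flow report,
    diagnostic-accuracy statistics (sensitivity, specificity, predictive
    values, likelihood ratios) with exact Clopper-Pearson confidence
    intervals, ROC-based cutpoint selection, a sample-size calculator for
    sensitivity estimation, and a latent-trait synthetic-respondent
    generator so every pipeline stage is testable without access to the
    restricted study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
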