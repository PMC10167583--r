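Package: vtenlp
Title: Rule-Based Detection of Venous Thromboembolism from Electronic
    Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A configurable rule-based clinical natural language processing
    pipeline that detects deep vein thrombosis and pulmonary embolism from
    multi-document inpatient records, classifies events as on-admission
    versus new-onset in-hospital, and evaluates detection against a manual
    reference standard with a full diagnostic-accuracy toolbox (sensitivity,
    specificity, predictive values, likelihood ratios with log-method and
    bootstrap intervals, AUC with the DeLong test, F1 comparison, Cohen's
    kappa, relative diagnostic likelihood ratios, and Bonferroni-adjusted
    stratified reports). Ships a bilingual (English/Chinese) default
    knowledge base and a seeded synthetic-corpus generator with realistic
    assertion error modes, so every pipeline stage is testable without
    protected health data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
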