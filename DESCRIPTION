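Package: triagecost
Title: Diagnostic Accuracy and Imaging Costs for Tomosynthesis-Based
    Triage of Suspected Chest Lesions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating a chest-imaging triage pathway in which
    digital tomosynthesis (DTS) is read after an equivocal chest radiograph
    (CXR) and an ordinal 1-5 confidence score routes each patient either to
    radiographic follow-up (scores 1-2) or to computed tomography (scores
    3-5). Provides confidence-score classification into confusion counts,
    reader-performance statistics (sensitivity, specificity, accuracy,
    predictive values, nonparametric ROC area with Hanley-McNeil standard
    errors and correlated-curve comparison, McNemar and Yates-corrected
    chi-square tests, weighted kappa, paired interpretation-time tests),
    activity-based per-examination costing with exact cent arithmetic,
    differential annual cost and savings between utilisation scenarios,
    contribution-margin break-even analysis, and a seeded synthetic cohort
    generator with modality- and truth-conditional score distributions for
    testing every stage without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
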