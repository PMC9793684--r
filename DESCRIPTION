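Package: taskpotency
Title: Task-Potency Connectomes, Normative Deviation Mapping, and
    Out-of-Sample Brain-Behavior Canonical Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying task-induced modulation of the
    functional connectome ("task potency"): regularized partial
    correlation connectomes with Gaussian-gamma mixture normalization,
    rest-from-task subtraction, empirical-Bayes multi-site
    harmonization, per-edge normative models of potency against age and
    sex with out-of-sample deviation Z-scores, case-control
    atypicality statistics, cross-task similarity of deviation
    patterns, and robust out-of-sample canonical correlation analysis
    linking connectome deviations to behavioral scales with a
    within-site permutation null. Includes a multi-site synthetic
    cohort simulator so the full pipeline is testable without access
    to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    randomForest
Suggests:
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
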