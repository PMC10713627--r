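Package: ttescreen
Title: High-Throughput Target Trial Emulation for Drug-Repurposing Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Emulates target trials at scale from longitudinal patient event
    records to screen approved drugs for new indications. Implements new-user
    cohort construction with active- and random-comparator arms, machine
    learning propensity score model spaces with balance-aware cross-validated
    model selection, trimmed stabilized inverse probability of treatment
    weighting, standardized mean difference balance diagnostics, weighted Cox
    and Kaplan-Meier effect estimation with bootstrap aggregation across
    emulations, Bonferroni-screened candidate ranking, and a fully specified
    confounded Weibull survival simulation study with potential-outcomes
    ground truth for evaluating estimator bias, variance and coverage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    glmnet,
    jsonlite,
    pROC,
    stats,
    survival,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
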