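Package: wsvm
Title: Weighted Support Vector Machines with Point-Biserial Feature Weighting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary clinical-outcome classification with the weighted support
    vector machine (w-SVM): point-biserial correlations between each predictor
    and a dichotomous response are normalised into unit-trace feature weights,
    the columns of the design matrix are scaled by these weights, and an
    RBF-kernel support vector machine is trained on the weighted data by
    solving the soft-margin dual quadratic program. Includes a loader for the
    UCI Cleveland heart-disease CSV dialect, a synthetic-data generator that
    emulates its mixed continuous/categorical structure, 10-fold
    cross-validated hyperparameter tuning, Monte-Carlo cross-validation over
    train:test splitting ratios with seven performance indices (accuracy,
    misclassification error rate, sensitivity, specificity, positive and
    negative predictive value, Jaccard index), and a paired comparison harness
    against naive Bayes, random forest and unweighted SVM baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    e1071,
    kernlab,
    optparse,
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
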