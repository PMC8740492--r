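Package: hobclass
Title: Consensus Random-Forest Classification of Human Oral Bioavailability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A QSAR workflow for classifying small molecules as high or low
    human oral bioavailability (%F) at a configurable cutoff. Provides
    interval-aware labeling of measured %F values, two-stage structure and
    fingerprint deduplication, 2D molecular descriptor computation with
    degenerate-feature filtering, Tanimoto similarity audits between training
    and test chemistry, a five-member cross-validated random-forest consensus
    classifier with equal-weight voting and grid-searched hyperparameters, a
    full evaluation suite (sensitivity, specificity, accuracy, MCC, F1,
    ROC/AUC, Yule's Q ensemble diversity), exact tree-path Shapley feature
    attributions with consensus importance ranking and dependence summaries,
    and a PCA convex-hull applicability domain. A synthetic-data generator
    with known label rules makes the whole pipeline testable without
    chemistry downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineR,
    ChemmineOB,
    randomForest,
    jsonlite,
    Rcpp,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
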