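Package: gwolfsel
Title: Hybrid Grey Wolf / Simulated Annealing Feature Selection for Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for two-class gene expression studies
    (cancer versus normal) built around a binary grey wolf optimizer hybridized
    with simulated annealing. Candidate gene subsets are scored by a
    SMOTE-balanced, weighted-voting ensemble of four classifiers (gradient
    boosted trees, support vector machine, random forest, decision tree) with a
    feature-count penalty. Includes dataset merging with empirical-Bayes batch
    adjustment and a PCA diagnostic, differential expression screening with
    log-fold-change and adjusted-p thresholds, genetic-algorithm and Monte
    Carlo/incremental feature selection baselines, intersection of selected and
    differentially expressed gene sets, and a synthetic expression data
    generator with planted informative genes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    sva,
    ranger,
    e1071,
    rpart,
    xgboost,
    nnet,
    class,
    glmnet,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
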