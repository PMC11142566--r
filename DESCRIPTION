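Package: kmsmote
Title: Cluster-Wise Hybrid Resampling for Imbalanced Clinical Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Balances heavily imbalanced binary clinical tables with a
    cluster-wise hybrid resampler: K-means partitions the training data
    (cluster count chosen by an elbow scan of within-cluster sums of
    squares), SMOTE equalizes class counts inside each cluster, and an
    edited-nearest-neighbour cleaning pass (3- or 5-neighbour rule)
    removes boundary noise before the clusters are merged. Ships the
    classical baselines (SMOTE, NearMiss-1, SMOTE+ENN, SMOTE+KNN), a
    leakage-safe evaluation harness over nine standard classifiers,
    permutation feature importance, expert-panel tabulation (interview
    frequencies and weighted survey scores), model-versus-expert
    concordance reports, and a seeded generator of thyroid-panel-like
    synthetic tables for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    rpart,
    randomForest,
    ranger,
    nnet,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    mclust,
    optparse
Config/testthat/edition: 3
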