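#' Apply a named balancing technique to a training table
#'
#' Dispatch helper shared by [run_experiment()] and the command-line
#' wrapper. `"none"` returns the table unchanged.
#'
#' @param train Training [labeled_table()].
#' @param balancer One of `"none"`, `"smote"`, `"nearmiss"`, `"smote-enn"`,
#'   `"smote-knn"`, `"kmeans-smote-enn"`, `"kmeans-smote-knn"`.
#' @param cfg A [resample_config()].
#' @param k_max Elbow-scan bound for the cluster-wise variants.
#' @return The balanced [labeled_table()].
#' @export
apply_balancer <- function(train, balancer, cfg = resample_config(),
                           k_max = 10L) {
  balancer <- match.arg(balancer,
    c("none", "smote", "nearmiss", "smote-enn", "smote-knn",
      "kmeans-smote-enn", "kmeans-smote-knn"))
  switch(balancer,
    "none" = train,
    "smote" = smote(train, cfg),
    "nearmiss" = nearmiss(train, cfg),
    "smote-enn" = smote_enn(train, cfg),
    "smote-knn" = smote_knn(train, cfg),
    "kmeans-smote-enn" = cluster_balance(train, "enn", cfg,
                                         k_max = k_max)$table,
    "kmeans-smote-knn" = cluster_balance(train, "knn", cfg,
                                         k_max = k_max)$table
  )
}

#' Run a balancing + classification experiment
#'
#' The full evaluation protocol: split 80:20, standardize (fitted on the
#' training side only), balance the training split with the named
#' technique, run stratified k-fold cross-validation on the balanced
#' training data for stability statistics, then fit each classifier on the
#' full balanced training data and report headline metrics on the untouched
#' test split. Balancing never sees a test row.
#'
#' @param data A [labeled_table()] (cleaned).
#' @param balancer Balancing technique name; see [apply_balancer()].
#' @param classifiers List of [classifier_spec()]s (default: all nine).
#' @param folds Cross-validation folds on the balanced training data
#'   (default 5; `0` skips CV).
#' @param seed Integer seed driving the split, the balancer, fold
#'   assignment, and every stochastic classifier.
#' @param ratio Train fraction of the initial split.
#' @param cfg A [resample_config()] for the balancer (its seed is derived
#'   from `seed`).
#' @param average Metric averaging mode, `"weighted"` (default) or
#'   `"binary"`.
#' @return A data.frame, one row per classifier, with test-set `accuracy`,
#'   `precision`, `recall`, `f1`, `auc` (the layout of the published
#'   comparison tables), the minority-class `recall_minority`, and CV
#'   `cv_accuracy_mean` / `cv_accuracy_sd` when `folds > 0`. The attribute
#'   `"reports"` carries the full [summary_metrics()] objects.
#' @export
run_experiment <- function(data, balancer = "none",
                           classifiers = default_classifier_specs(),
                           folds = 5L, seed = 1L, ratio = 0.8,
                           cfg = resample_config(), average = "weighted") {
  if (inherits(classifiers, "classifier_spec")) {
    classifiers <- list(classifiers)
  }
  if (is.null(names(classifiers))) {
    names(classifiers) <- vapply(classifiers, function(s) s$name,
                                 character(1))
  }
  sp <- split_table(data, ratio = ratio, seed = seed)
  std <- standardize(sp$train, sp$test)
  train_s <- std$train
  test_s <- std$extra[[1]]
  bcfg <- resample_config(k_neighbors1 = cfg$k_neighbors1,
                          k_neighbors2 = cfg$k_neighbors2,
                          strategy = cfg$strategy,
                          seed = derive_seed(seed, 101L))
  bal <- apply_balancer(train_s, balancer, bcfg)

  fold_id <- if (folds > 0L) {
    with_seed(derive_seed(seed, 202L), {
      id <- integer(length(bal$y))
      for (cl in c(0L, 1L)) {
        rows <- which(bal$y == cl)
        id[rows] <- sample(rep_len(seq_len(folds), length(rows)))
      }
      id
    })
  } else NULL

  reports <- list()
  rows <- list()
  for (nm in names(classifiers)) {
    spec <- classifiers[[nm]]
    cls_seed <- derive_seed(seed, 303L)
    cv_acc <- if (folds > 0L) {
      vapply(seq_len(folds), function(f) {
        tr <- fold_id != f
        if (length(unique(bal$y[tr])) < 2L) return(NA_real_)
        fit <- fit_classifier(spec, bal$X[tr, , drop = FALSE], bal$y[tr],
                              seed = cls_seed)
        mean(predict(fit, bal$X[!tr, , drop = FALSE]) == bal$y[!tr])
      }, numeric(1))
    } else NULL
    fit <- fit_classifier(spec, bal$X, bal$y, seed = cls_seed)
    sc <- classifier_score(fit, test_s$X)
    pred <- as.integer(sc >= 0.5)
    rep <- summary_metrics(test_s$y, pred, average = average, scores = sc)
    reports[[nm]] <- rep
    rows[[nm]] <- data.frame(
      model = nm, balancer = balancer,
      accuracy = rep$accuracy, precision = rep$precision,
      recall = rep$recall, f1 = rep$f1, auc = rep$auc,
      recall_minority = rep$per_class["1", "recall"],
      cv_accuracy_mean = if (is.null(cv_acc)) NA_real_
                         else mean(cv_acc, na.rm = TRUE),
      cv_accuracy_sd = if (is.null(cv_acc)) NA_real_
                       else stats::sd(cv_acc, na.rm = TRUE)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}
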