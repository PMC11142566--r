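#' Permutation feature importance
#'
#' Model-agnostic global importance: the score of a feature is the mean
#' drop in a performance metric over `repeats` seeded shuffles of that
#' feature's column, evaluated on the supplied table. Serial ranks are
#' assigned by descending score with ties broken by feature order, so the
#' ranking is deterministic.
#'
#' Any externally computed per-feature score vector (e.g. Shapley-value
#' attributions) can be turned into the same ranking object with
#' [importance_ranking()].
#'
#' @param fitted A `fitted_classifier` from [fit_classifier()].
#' @param table A [labeled_table()] to evaluate on (typically held-out).
#' @param metric `"accuracy"` (default), `"f1"`, or `"auc"`.
#' @param repeats Number of shuffles per feature.
#' @param seed Integer seed for the shuffles.
#' @return An `importance_ranking` data.frame with columns `feature`,
#'   `score`, `serial`.
#' @export
permutation_importance <- function(fitted, table, metric = c("accuracy",
                                                             "f1", "auc"),
                                   repeats = 5L, seed = 1L) {
  metric <- match.arg(metric)
  if (!inherits(fitted, "fitted_classifier")) {
    stop_kmsmote("`fitted` must come from fit_classifier()")
  }
  eval_metric <- function(X) {
    sc <- classifier_score(fitted, X)
    switch(metric,
      accuracy = mean(as.integer(sc >= 0.5) == table$y),
      f1 = summary_metrics(table$y, as.integer(sc >= 0.5),
                           average = "binary")$f1,
      auc = roc_and_auc(table$y, sc)$auc)
  }
  base <- eval_metric(table$X)
  n <- nrow(table$X)
  scores <- with_seed(seed, {
    vapply(seq_len(ncol(table$X)), function(j) {
      drops <- vapply(seq_len(repeats), function(r) {
        Xp <- table$X
        Xp[, j] <- Xp[sample.int(n), j]
        base - eval_metric(Xp)
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  })
  importance_ranking(colnames(table$X), scores)
}

#' Build an importance ranking from raw scores
#'
#' @param features Character vector of feature names.
#' @param scores Numeric per-feature scores (larger = more important).
#' @return An `importance_ranking` data.frame with `feature`, `score`, and
#'   1-based `serial` (descending score, ties by feature order).
#' @export
importance_ranking <- function(features, scores) {
  stopifnot(length(features) == length(scores))
  ord <- order(-scores, seq_along(scores))
  serial <- integer(length(scores))
  serial[ord] <- seq_along(scores)
  structure(data.frame(feature = as.character(features), score = scores,
                       serial = serial, stringsAsFactors = FALSE),
            class = c("importance_ranking", "data.frame"))
}
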