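#' Confusion matrix for binary predictions
#'
#' Counts with class 1 as the positive class: `tp` = predicted 1, actual 1;
#' `tn` = predicted 0, actual 0; `fp` = predicted 1, actual 0; `fn` =
#' predicted 0, actual 1.
#'
#' @param y_true,y_pred Equal-length vectors with entries in `{0, 1}`.
#' @return An object of class `confusion_matrix` (list `tp`, `tn`, `fp`,
#'   `fn`).
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop_kmsmote("y_true and y_pred differ in length")
  }
  if (!all(c(y_true, y_pred) %in% c(0, 1))) {
    stop_kmsmote("labels and predictions must be 0/1")
  }
  structure(
    list(tp = sum(y_true == 1 & y_pred == 1),
         tn = sum(y_true == 0 & y_pred == 0),
         fp = sum(y_true == 0 & y_pred == 1),
         fn = sum(y_true == 1 & y_pred == 0)),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, 2, byrow = TRUE,
              dimnames = list(actual = c("0", "1"),
                              predicted = c("0", "1")))
  print(m)
  invisible(x)
}

# Precision/recall/F1 treating class `cls` as positive, with the 0/0 -> 0
# convention.
prf_one_class <- function(y_true, y_pred, cls) {
  tp <- sum(y_true == cls & y_pred == cls)
  fp <- sum(y_true != cls & y_pred == cls)
  fn <- sum(y_true == cls & y_pred != cls)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Summary classification metrics
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN); precision = TP/(TP+FP); recall =
#' TP/(TP+FN); F1 = harmonic mean of precision and recall, computed per
#' class before averaging. `average = "weighted"` (the default reporting
#' mode) weights the per-class scores by class support, which is why
#' reported precision can exceed accuracy on imbalanced test sets;
#' `"binary"` reports the class-1 scores only. Division by zero yields 0.
#'
#' @param y_true,y_pred Equal-length 0/1 vectors.
#' @param average `"weighted"` or `"binary"`.
#' @param scores Optional class-1 scores; when supplied, ROC/PR curves and
#'   AUC are included.
#' @return An object of class `metrics_report`: list with `accuracy`,
#'   `precision`, `recall`, `f1`, `confusion`, `average`, `per_class`, and
#'   (when `scores` is given) `auc`, `roc`, `pr`.
#' @export
summary_metrics <- function(y_true, y_pred, average = c("weighted", "binary"),
                            scores = NULL) {
  average <- match.arg(average)
  cm <- confusion(y_true, y_pred)
  acc <- (cm$tp + cm$tn) / length(y_true)
  per_class <- rbind("0" = prf_one_class(y_true, y_pred, 0),
                     "1" = prf_one_class(y_true, y_pred, 1))
  if (average == "binary") {
    prf <- per_class["1", ]
  } else {
    w <- c(sum(y_true == 0), sum(y_true == 1)) / length(y_true)
    prf <- colSums(per_class * w)
  }
  rep <- list(accuracy = acc, precision = unname(prf["precision"]),
              recall = unname(prf["recall"]), f1 = unname(prf["f1"]),
              confusion = cm, average = average, per_class = per_class)
  if (!is.null(scores)) {
    roc <- roc_and_auc(y_true, scores)
    rep$auc <- roc$auc
    rep$roc <- roc$points
    rep$pr <- pr_curve(y_true, scores)
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> accuracy %.4f  precision %.4f  recall %.4f  f1 %.4f",
              x$accuracy, x$precision, x$recall, x$f1))
  if (!is.null(x$auc)) cat(sprintf("  auc %.4f", x$auc))
  cat("  (", x$average, " averaging)\n", sep = "")
  invisible(x)
}

#' ROC curve and trapezoid AUC
#'
#' Sweeps thresholds over the distinct score values (ties grouped into one
#' step), accumulating (FPR, TPR) points from (0, 0) to (1, 1), and
#' integrates by the trapezoid rule — numerically identical to the
#' normalised Mann-Whitney rank-sum statistic.
#'
#' @param y_true 0/1 vector containing at least one of each class.
#' @param scores Numeric scores, larger meaning more class-1-like.
#' @return List with `points` (data.frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_and_auc <- function(y_true, scores) {
  check_two_classes(y_true, scores)
  sw <- score_sweep(y_true, scores)
  fpr <- c(0, sw$cum_fp / sw$n0)
  tpr <- c(0, sw$cum_tp / sw$n1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr,
                           threshold = c(Inf, sw$thresholds)),
       auc = auc)
}

#' Precision-recall curve
#'
#' One (recall, precision) point per distinct score threshold, from the
#' strictest threshold to predicting everything positive.
#'
#' @inheritParams roc_and_auc
#' @return Data.frame with `recall`, `precision`, `threshold`.
#' @export
pr_curve <- function(y_true, scores) {
  check_two_classes(y_true, scores)
  sw <- score_sweep(y_true, scores)
  data.frame(recall = sw$cum_tp / sw$n1,
             precision = sw$cum_tp / (sw$cum_tp + sw$cum_fp),
             threshold = sw$thresholds)
}

check_two_classes <- function(y_true, scores) {
  if (length(y_true) != length(scores)) {
    stop_kmsmote("labels and scores differ in length")
  }
  if (length(unique(y_true)) < 2L) {
    stop_kmsmote("curves need at least one positive and one negative")
  }
}

# Cumulative TP/FP counts when predicting positive at score >= threshold,
# thresholds descending over the distinct scores.
score_sweep <- function(y_true, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]
  s <- scores[ord]
  last_of_group <- which(!duplicated(s, fromLast = TRUE))  # grouped ties
  list(thresholds = s[last_of_group],
       cum_tp = cumsum(y == 1)[last_of_group],
       cum_fp = cumsum(y == 0)[last_of_group],
       n1 = sum(y == 1), n0 = sum(y == 0))
}
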