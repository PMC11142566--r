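#' Tabulate structured-interview feature selections
#'
#' Each of `d` doctors marks (1) or does not mark (0) every feature as a
#' disease indicator. A feature's frequency is its row sum; its rank is 1
#' when every doctor selected it, 2 when at least half (but not all) did,
#' and 3 otherwise — the scheme that reproduces the published five-doctor
#' panel exactly (frequency 5 -> rank 1, 3-4 -> rank 2, 0-2 -> rank 3).
#'
#' @param m Binary matrix or data.frame, features x doctors, with feature
#'   names as row names (or a `feature` column).
#' @return Data.frame with `feature`, `frequency`, `rank`.
#' @export
interview_rank <- function(m) {
  if (is.data.frame(m) && "feature" %in% names(m)) {
    rn <- m$feature
    m <- as.matrix(m[setdiff(names(m), "feature")])
    rownames(m) <- rn
  } else {
    m <- as.matrix(m)
  }
  if (ncol(m) < 1L) stop_kmsmote("at least one doctor column is required")
  if (!all(m %in% c(0, 1))) stop_kmsmote("interview entries must be 0/1")
  d <- ncol(m)
  freq <- rowSums(m)
  rank <- ifelse(freq == d, 1L, ifelse(freq >= ceiling(d / 2), 2L, 3L))
  data.frame(feature = rownames(m) %||% sprintf("f%d", seq_len(nrow(m))),
             frequency = unname(freq), rank = unname(rank),
             stringsAsFactors = FALSE)
}

#' Score weighted survey responses
#'
#' Respondents place each feature in a High / Medium / Low importance
#' category; the feature score is the weighted count `3*high + 2*medium +
#' 1*low` (weights configurable). Serial order is by descending score with
#' ties broken by feature order.
#'
#' @param counts Data.frame with columns `feature`, `high`, `medium`, `low`
#'   (case-insensitive).
#' @param weights Length-3 numeric weights for (high, medium, low).
#' @param respondents Expected per-feature respondent total; defaults to
#'   the most common row sum. Rows that do not sum to it raise a warning.
#' @return An `importance_ranking` data.frame (`feature`, `score`,
#'   `serial`).
#' @export
survey_score <- function(counts, weights = c(3, 2, 1), respondents = NULL) {
  names(counts) <- tolower(names(counts))
  need <- c("feature", "high", "medium", "low")
  if (!all(need %in% names(counts))) {
    stop_kmsmote("counts needs columns: ", paste(need, collapse = ", "))
  }
  cm <- as.matrix(counts[c("high", "medium", "low")])
  if (any(cm < 0) || any(cm != round(cm))) {
    stop_kmsmote("category counts must be nonnegative integers")
  }
  totals <- rowSums(cm)
  respondents <- respondents %||%
    as.numeric(names(sort(table(totals), decreasing = TRUE))[1])
  if (any(totals != respondents)) {
    warning("some rows do not sum to the respondent total of ",
            respondents, call. = FALSE)
  }
  importance_ranking(counts$feature, as.numeric(cm %*% weights))
}

#' Cut importance scores into High / Medium / Low levels
#'
#' `method = "counts"` (default) assigns the top `level_counts[1]` features
#' by score to High, the next `level_counts[2]` to Medium, and the rest to
#' Low — the partition used by the published concordance table (2/7/11 for
#' 20 features). `method = "gaps"` instead cuts at the two largest drops in
#' the sorted score sequence. Ties follow serial order, so a feature with a
#' strictly higher score never lands in a lower level.
#'
#' @param ranking An `importance_ranking` (or data.frame with `feature`,
#'   `score`, `serial`).
#' @param level_counts Length-3 integer partition summing to the feature
#'   count (used by `method = "counts"`).
#' @param method `"counts"` or `"gaps"`.
#' @return The ranking with a `level` factor column (`High`, `Medium`,
#'   `Low`) added.
#' @export
assign_levels <- function(ranking, level_counts = c(2L, 7L, 11L),
                          method = c("counts", "gaps")) {
  method <- match.arg(method)
  d <- nrow(ranking)
  if (method == "counts") {
    if (sum(level_counts) != d) {
      stop_kmsmote("level_counts sums to ", sum(level_counts),
                   " but there are ", d, " features")
    }
    bounds <- cumsum(level_counts)
    lv <- factor(ifelse(ranking$serial <= bounds[1], "High",
                        ifelse(ranking$serial <= bounds[2], "Medium",
                               "Low")),
                 levels = c("High", "Medium", "Low"))
  } else {
    ord <- order(ranking$serial)
    s <- ranking$score[ord]
    drops <- -diff(s)
    cutpts <- sort(order(-drops, seq_along(drops))[1:2])
    lv_ord <- cut(seq_len(d), breaks = c(0, cutpts, d),
                  labels = c("High", "Medium", "Low"))
    lv <- factor(rep(NA, d), levels = c("High", "Medium", "Low"))
    lv[ord] <- lv_ord
  }
  ranking$level <- lv
  ranking
}

#' Concordance between a model ranking and an expert ranking
#'
#' Compares two level-annotated rankings over the same feature set: a
#' per-feature level match flag, the match fraction (symmetric in the two
#' arguments), the Spearman rank correlation of the serial orders, and the
#' list of level disagreements.
#'
#' @param xai Data.frame with `feature`, `serial`, `level` (model side).
#' @param expert Data.frame with the same columns (expert side).
#' @return An object of class `alignment_report`: list with `features`
#'   (per-feature data.frame), `match_fraction`, `spearman`,
#'   `disagreements`.
#' @export
alignment_report <- function(xai, expert) {
  if (!setequal(xai$feature, expert$feature)) {
    stop_kmsmote("the two rankings cover different feature sets")
  }
  expert <- expert[match(xai$feature, expert$feature), ]
  match_flag <- as.character(xai$level) == as.character(expert$level)
  feats <- data.frame(
    feature = xai$feature,
    xai_level = as.character(xai$level),
    expert_level = as.character(expert$level),
    xai_serial = xai$serial, expert_serial = expert$serial,
    level_match = match_flag, stringsAsFactors = FALSE
  )
  structure(
    list(features = feats,
         match_fraction = mean(match_flag),
         spearman = stats::cor(xai$serial, expert$serial,
                               method = "spearman"),
         disagreements = feats$feature[!match_flag]),
    class = "alignment_report"
  )
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf("<alignment_report> level match %d/%d (%.2f), spearman %.3f\n",
              sum(x$features$level_match), nrow(x$features),
              x$match_fraction, x$spearman))
  if (length(x$disagreements)) {
    cat("  disagreements:", paste(x$disagreements, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Bundled expert-panel fixtures
#'
#' Small CSVs shipped with the package: the five-doctor structured
#' interview selections, the 30-respondent survey category counts, and the
#' published model-versus-expert level/serial table used as a concordance
#' reference.
#'
#' @return Data.frames read from the package's `extdata` directory.
#' @export
thyroid_expert_interviews <- function() {
  utils::read.csv(system.file("extdata", "expert_interviews.csv",
                              package = "kmsmote"),
                  check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname thyroid_expert_interviews
#' @export
thyroid_expert_survey <- function() {
  utils::read.csv(system.file("extdata", "expert_survey.csv",
                              package = "kmsmote"),
                  check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname thyroid_expert_interviews
#' @export
thyroid_importance_levels <- function() {
  utils::read.csv(system.file("extdata", "importance_levels.csv",
                              package = "kmsmote"),
                  check.names = FALSE, stringsAsFactors = FALSE)
}
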