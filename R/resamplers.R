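#' Resampling configuration
#'
#' Bundles the neighbour counts, metric, seed, and target-ratio strategy
#' shared by the resamplers.
#'
#' @param k_neighbors1 SMOTE interpolation neighbours (default 5).
#' @param k_neighbors2 Editing neighbours; `NULL` (default) lets each editor
#'   use its conventional value: 3 for ENN cleaning, 5 for KNN cleaning.
#' @param metric Distance name; only `"euclidean"` is supported.
#' @param seed Integer seed driving every random draw; `NULL` uses the
#'   current RNG stream.
#' @param strategy `"equalize"` (post-SMOTE minority count equals the
#'   majority count) or a positive integer target minority count.
#' @return An object of class `resample_config`.
#' @export
resample_config <- function(k_neighbors1 = 5L, k_neighbors2 = NULL,
                            metric = "euclidean", seed = NULL,
                            strategy = "equalize") {
  if (k_neighbors1 < 1L) stop_kmsmote("k_neighbors1 must be >= 1")
  if (!is.null(k_neighbors2) && k_neighbors2 < 1L) {
    stop_kmsmote("k_neighbors2 must be >= 1")
  }
  if (!identical(metric, "euclidean")) {
    stop_kmsmote("only the euclidean metric is supported")
  }
  if (!(identical(strategy, "equalize") ||
        (is.numeric(strategy) && strategy >= 1))) {
    stop_kmsmote("strategy must be 'equalize' or a positive count")
  }
  structure(
    list(k_neighbors1 = as.integer(k_neighbors1),
         k_neighbors2 = if (is.null(k_neighbors2)) NULL
                        else as.integer(k_neighbors2),
         metric = metric, seed = seed, strategy = strategy),
    class = "resample_config"
  )
}

# The locally rarer class; ties resolve to class 1 (then nothing is done).
minority_class <- function(table) {
  cc <- class_counts(table)
  if (cc[["1"]] <= cc[["0"]]) 1L else 0L
}

#' SMOTE oversampling
#'
#' Creates synthetic minority rows by linear interpolation: each synthetic
#' row is `x + lambda * (nbr - x)` where `x` is a minority row, `nbr` one of
#' its `k_neighbors1` nearest minority neighbours, and `lambda` is uniform
#' on `[0, 1)`. Base/neighbour pairs are drawn uniformly from the seeded
#' generator until the strategy's target count is met, so under the default
#' `"equalize"` strategy the output classes have equal size. Majority rows
#' are passed through verbatim; when the minority has at most `k_neighbors1`
#' rows the neighbour count is reduced to `minority - 1`.
#'
#' The minority class is determined from the table itself (the rarer label);
#' an already balanced table is returned unchanged.
#'
#' @param train Training [labeled_table()] (never the test split).
#' @param cfg A [resample_config()].
#' @return A [labeled_table()]: the original rows followed by the synthetic
#'   rows. The attribute `"smote_pairs"` records, for each synthetic row,
#'   the base and neighbour row indices (into `train`) and `lambda`.
#' @export
smote <- function(train, cfg = resample_config()) {
  cc <- class_counts(train)
  mc <- minority_class(train)
  n_min <- cc[[as.character(mc)]]
  n_maj <- nrow(train$X) - n_min
  target <- if (identical(cfg$strategy, "equalize")) n_maj
            else as.integer(cfg$strategy)
  n_syn <- target - n_min
  if (n_syn <= 0L) return(train)
  if (n_min < 2L) {
    stop_kmsmote("cannot interpolate: minority class has ", n_min, " row(s)")
  }
  min_rows <- which(train$y == mc)
  k <- min(cfg$k_neighbors1, n_min - 1L)
  nn <- knn_query(train$X[min_rows, , drop = FALSE], k = k,
                  exclude_self = TRUE)
  draw <- with_seed(cfg$seed, {
    list(base = sample.int(n_min, n_syn, replace = TRUE),
         nbr = sample.int(k, n_syn, replace = TRUE),
         lambda = stats::runif(n_syn))
  })
  base_idx <- min_rows[draw$base]
  nbr_idx <- min_rows[nn$idx[cbind(draw$base, draw$nbr)]]
  Xb <- train$X[base_idx, , drop = FALSE]
  Xn <- train$X[nbr_idx, , drop = FALSE]
  Xs <- Xb + draw$lambda * (Xn - Xb)
  out <- labeled_table(rbind(train$X, Xs),
                       c(train$y, rep(mc, n_syn)), train$schema)
  attr(out, "smote_pairs") <- data.frame(base = base_idx, neighbor = nbr_idx,
                                         lambda = draw$lambda)
  out
}

# Shared edited-nearest-neighbour cleaning rule. For every row, the k
# nearest neighbours (self excluded) are found in the *input* table; rows
# whose label disagrees with the strict majority label of those neighbours
# are deleted, simultaneously, from both classes. A tied vote keeps the row.
edit_nn <- function(table, k) {
  n <- nrow(table$X)
  if (n <= k) stop_kmsmote("editing needs more than k = ", k, " rows")
  if (length(unique(table$y)) < 2L) return(table)
  nn <- knn_query(table$X, k = k, exclude_self = TRUE)
  votes1 <- matrix(table$y[nn$idx], n, k)
  n_other <- rowSums(votes1 != table$y)
  keep <- n_other <= k / 2      # delete only on strict majority disagreement
  out <- subset_rows(table, which(keep))
  if (any(class_counts(out) == 0L)) {
    warning("editing emptied a class", call. = FALSE)
    attr(out, "emptied_class") <- TRUE
  }
  attr(out, "kept") <- which(keep)
  out
}

#' Edited-nearest-neighbour (ENN) cleaning
#'
#' Deletes every row whose label differs from the strict majority label of
#' its `k_neighbors2` nearest neighbours (3 by default), computed against
#' the original table with all deletions applied simultaneously. Both
#' classes are subject to editing; a tied vote keeps the row. The attribute
#' `"kept"` on the result holds the surviving input row indices.
#'
#' @param table A [labeled_table()].
#' @param cfg A [resample_config()]; `k_neighbors2 = NULL` means 3.
#' @return The edited [labeled_table()].
#' @export
enn_clean <- function(table, cfg = resample_config()) {
  edit_nn(table, cfg$k_neighbors2 %||% 3L)
}

#' KNN editing
#'
#' The same disagreement-deletion rule as [enn_clean()] evaluated with 5
#' neighbours by default.
#'
#' @inheritParams enn_clean
#' @return The edited [labeled_table()].
#' @export
knn_clean <- function(table, cfg = resample_config()) {
  edit_nn(table, cfg$k_neighbors2 %||% 5L)
}

#' NearMiss-1 undersampling
#'
#' Scores each majority row by its mean distance to its 3 nearest minority
#' rows and keeps the `minority-count` majority rows with the smallest
#' score, so the output classes are equal in size. Minority rows are
#' untouched.
#'
#' @param train Training [labeled_table()] with both classes non-empty.
#' @param cfg A [resample_config()] (only the metric is consulted).
#' @return A [labeled_table()] with equal class counts, rows in their
#'   original order.
#' @export
nearmiss <- function(train, cfg = resample_config()) {
  cc <- class_counts(train)
  if (any(cc == 0L)) stop_kmsmote("both classes must be non-empty")
  mc <- minority_class(train)
  min_rows <- which(train$y == mc)
  maj_rows <- which(train$y != mc)
  if (length(maj_rows) <= length(min_rows)) return(train)
  k_ref <- min(3L, length(min_rows))
  nn <- knn_query(train$X[min_rows, , drop = FALSE],
                  train$X[maj_rows, , drop = FALSE], k = k_ref)
  score <- rowMeans(nn$dist)
  keep_maj <- maj_rows[order(score, seq_along(maj_rows))[
    seq_len(length(min_rows))]]
  subset_rows(train, sort(c(min_rows, keep_maj)))
}

#' Hybrid SMOTE + editing resamplers
#'
#' [smote_enn()] runs [smote()] and then [enn_clean()] on the union of the
#' original and synthetic rows; [smote_knn()] uses [knn_clean()] instead.
#' These are the non-clustered hybrids; see [cluster_balance()] for the
#' cluster-wise variant.
#'
#' @inheritParams smote
#' @return The resampled and edited [labeled_table()].
#' @export
smote_enn <- function(train, cfg = resample_config()) {
  enn_clean(smote(train, cfg), cfg)
}

#' @rdname smote_enn
#' @export
smote_knn <- function(train, cfg = resample_config()) {
  knn_clean(smote(train, cfg), cfg)
}
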