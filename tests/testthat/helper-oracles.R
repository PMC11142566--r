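# Independent brute-force reference implementations used to check the
# package's neighbour-based operations, plus small fixture builders.
# These deliberately use plain loops over full distance vectors, a
# different code path from the blockwise implementation under test.

oracle_dist <- function(X, q) {
  apply(X, 1, function(row) sqrt(sum((row - q)^2)))
}

oracle_knn <- function(X, queries, k, exclude_self = FALSE) {
  do.call(rbind, lapply(seq_len(nrow(queries)), function(i) {
    d <- oracle_dist(X, queries[i, ])
    if (exclude_self) d[i] <- Inf
    order(d, seq_along(d))[seq_len(k)]
  }))
}

# Edited-nearest-neighbour rule: keep a row unless a strict majority of its
# k nearest neighbours carries the other label. Simultaneous deletions.
oracle_edit <- function(X, y, k) {
  keep <- vapply(seq_len(nrow(X)), function(i) {
    d <- oracle_dist(X, X[i, ])
    d[i] <- Inf
    nb <- order(d, seq_along(d))[seq_len(k)]
    sum(y[nb] != y[i]) <= k / 2
  }, logical(1))
  which(keep)
}

# NearMiss-1: majority rows kept by smallest mean distance to their 3
# nearest minority rows.
oracle_nearmiss <- function(X, y) {
  mc <- if (sum(y == 1) <= sum(y == 0)) 1L else 0L
  min_rows <- which(y == mc)
  maj_rows <- which(y != mc)
  k <- min(3L, length(min_rows))
  score <- vapply(maj_rows, function(i) {
    mean(sort(oracle_dist(X[min_rows, , drop = FALSE], X[i, ]))[seq_len(k)])
  }, numeric(1))
  keep_maj <- maj_rows[order(score, seq_along(maj_rows))[
    seq_len(length(min_rows))]]
  sort(c(min_rows, keep_maj))
}

# AUC as the normalised Mann-Whitney rank-sum statistic (midranks for ties).
oracle_auc <- function(y, s) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  (sum(rank(s)[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# A small random labeled table with both classes present.
random_table <- function(n, d = 3L, p1 = 0.3, seed = 1L) {
  set.seed(seed)
  y <- c(0L, 1L, stats::rbinom(n - 2L, 1L, p1))
  X <- matrix(stats::rnorm(n * d), n, d,
              dimnames = list(NULL, sprintf("x%d", seq_len(d))))
  labeled_table(X, y)
}

# A 1-D table from coordinates and labels (column vector feature).
line_table <- function(coords, labels) {
  labeled_table(matrix(coords, ncol = 1, dimnames = list(NULL, "x")),
                labels)
}

# Small thyroid-like generator used by the unit tests (fast).
small_config <- function(seed = 1L, ...) {
  generator_config(n_majority = 600L, n_minority = 60L, seed = seed, ...)
}
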