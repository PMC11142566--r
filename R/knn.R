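#' Exact k-nearest-neighbour query
#'
#' Brute-force (exact) Euclidean nearest neighbours with a deterministic tie
#' rule: candidates at equal distance are ordered by ascending row index.
#' Distances are computed blockwise so memory stays bounded on large tables.
#'
#' @param X Numeric candidate matrix (rows are candidates).
#' @param queries Numeric query matrix; defaults to `X` itself.
#' @param k Number of neighbours to return per query.
#' @param exclude_self When `TRUE`, query row `i` is assumed to be candidate
#'   row `i` and is excluded from its own neighbour list (requires `queries`
#'   to be `X` or a row-aligned copy).
#' @return An object of class `neighbor_index`: list with integer matrix
#'   `idx` (queries x k, candidate row indices) and numeric matrix `dist`.
#' @export
knn_query <- function(X, queries = X, k, exclude_self = FALSE) {
  X <- as.matrix(X)
  queries <- as.matrix(queries)
  n_cand <- nrow(X)
  avail <- n_cand - as.integer(exclude_self)
  if (k > avail) {
    stop_kmsmote("k = ", k, " exceeds the ", avail,
                 " available neighbour candidates")
  }
  if (exclude_self && nrow(queries) != n_cand) {
    stop_kmsmote("exclude_self requires queries row-aligned with X")
  }
  nq <- nrow(queries)
  idx <- matrix(NA_integer_, nq, k)
  dst <- matrix(NA_real_, nq, k)
  x_sq <- rowSums(X^2)
  block <- max(1L, min(nq, floor(2e7 / n_cand)))
  for (start in seq(1L, nq, by = block)) {
    rows <- start:min(start + block - 1L, nq)
    Q <- queries[rows, , drop = FALSE]
    d2 <- outer(rowSums(Q^2), x_sq, "+") - 2 * tcrossprod(Q, X)
    d2[d2 < 0] <- 0
    for (ii in seq_along(rows)) {
      d <- d2[ii, ]
      if (exclude_self) d[rows[ii]] <- Inf
      ord <- order(d, seq_len(n_cand))[seq_len(k)]
      idx[rows[ii], ] <- ord
      dst[rows[ii], ] <- sqrt(d[ord])
    }
  }
  structure(list(idx = idx, dist = dst, k = k, exclude_self = exclude_self),
            class = "neighbor_index")
}
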