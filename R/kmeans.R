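#' K-means clustering (seeded k-means++ initialisation, Lloyd iterations)
#'
#' Centroids are initialised with the k-means++ rule from the seeded
#' generator, then refined by Lloyd iterations until the largest centroid
#' shift falls below `tol` or `max_iter` is reached. A cluster that empties
#' is reseeded to the point farthest from its assigned centroid. The
#' reported `ssd` (the "distortion" of an elbow scan) is the sum over rows
#' of the squared Euclidean distance to the assigned centroid.
#'
#' @param X Numeric matrix of observations.
#' @param k Number of clusters (`k <= nrow(X)`).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param max_iter Maximum Lloyd iterations.
#' @param tol Convergence tolerance on the maximum centroid displacement.
#' @return An object of class `kmeans_result`: list with `centroids`
#'   (k x d), `assignments` (length n), `ssd`, `iterations`, `converged`.
#' @export
kmeans_fit <- function(X, k, seed = NULL, max_iter = 300L, tol = 1e-4) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop_kmsmote("k = ", k, " exceeds the ", n, " rows")
  with_seed(seed, {
    C <- kmeanspp_init(X, k)
    assign_dist <- function(C) {
      d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C)
      d2[d2 < 0] <- 0
      cl <- max.col(-d2, ties.method = "first")
      list(cl = cl, d2 = d2[cbind(seq_len(n), cl)])
    }
    converged <- FALSE
    iter <- 0L
    a <- assign_dist(C)
    while (iter < max_iter) {
      iter <- iter + 1L
      C_new <- C
      for (j in seq_len(k)) {
        rows <- which(a$cl == j)
        if (length(rows) == 0L) {
          C_new[j, ] <- X[which.max(a$d2), ]    # reseed to the farthest point
        } else {
          C_new[j, ] <- colMeans(X[rows, , drop = FALSE])
        }
      }
      shift <- sqrt(max(rowSums((C_new - C)^2)))
      C <- C_new
      a <- assign_dist(C)
      if (shift < tol) {
        converged <- TRUE
        break
      }
    }
    structure(
      list(centroids = C, assignments = a$cl, ssd = sum(a$d2),
           iterations = iter, converged = converged),
      class = "kmeans_result"
    )
  })
}

# k-means++ seeding: first centre uniform, each next centre drawn with
# probability proportional to the squared distance to the nearest chosen one.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2, X[centers[1], ], "-")^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      centers[j + 1L] <- sample.int(n, 1L)
    } else {
      centers[j + 1L] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[centers[j + 1L], ], "-")^2))
  }
  X[centers, , drop = FALSE]
}

#' @export
print.kmeans_result <- function(x, ...) {
  cat("<kmeans_result> k = ", nrow(x$centroids), ", ssd = ",
      format(x$ssd), ", ", x$iterations, " iteration(s)",
      if (x$converged) " (converged)" else "", "\n", sep = "")
  invisible(x)
}

#' Elbow scan for the number of clusters
#'
#' Runs [kmeans_fit()] for every `k` in `1..k_max`, keeping the
#' best-of-`restarts` SSD, and picks the elbow — the sharpest decrease in
#' SSD. The default operationalisation maximises the discrete second
#' difference `ssd[k-1] - 2 ssd[k] + ssd[k+1]` over `k` in `2..(k_max-1)`;
#' `method = "knee"` instead maximises the distance from the SSD curve to
#' the chord joining its endpoints. A flat or non-decreasing curve raises a
#' warning and sets the `flat` flag (the rule's arg-max is still reported).
#'
#' @param X Numeric matrix of observations.
#' @param k_max Largest cluster count scanned (at least 3).
#' @param seed Integer seed.
#' @param restarts Independent initialisations per `k` (best SSD kept).
#' @param method `"second_diff"` (default) or `"knee"`.
#' @return An object of class `elbow_scan`: list with `ks`, `ssds`,
#'   `chosen_k`, `method`, `flat`.
#' @export
elbow_k <- function(X, k_max = 10L, seed = NULL, restarts = 5L,
                    method = c("second_diff", "knee")) {
  method <- match.arg(method)
  if (k_max < 3L) stop_kmsmote("k_max must be at least 3")
  ssds <- with_seed(seed, {
    vapply(seq_len(k_max), function(k) {
      min(vapply(seq_len(restarts), function(r) kmeans_fit(X, k)$ssd,
                 numeric(1)))
    }, numeric(1))
  })
  flat <- any(diff(ssds) > 0) || all(abs(diff(ssds)) < .Machine$double.eps)
  if (flat) {
    warning("SSD curve is not strictly decreasing; elbow may be unreliable",
            call. = FALSE)
  }
  inner <- 2:(k_max - 1L)
  chosen_k <- if (method == "second_diff") {
    curv <- ssds[inner - 1L] - 2 * ssds[inner] + ssds[inner + 1L]
    inner[which.max(curv)]
  } else {
    # distance from (k, ssd[k]) to the chord (1, ssd[1]) -- (k_max, ssd[k_max])
    x1 <- 1; y1 <- ssds[1]; x2 <- k_max; y2 <- ssds[k_max]
    num <- abs((y2 - y1) * inner - (x2 - x1) * ssds[inner] +
                 x2 * y1 - y2 * x1)
    inner[which.max(num)]
  }
  structure(list(ks = seq_len(k_max), ssds = ssds, chosen_k = chosen_k,
                 method = method, flat = flat),
            class = "elbow_scan")
}

#' @export
print.elbow_scan <- function(x, ...) {
  cat("<elbow_scan> k = 1..", max(x$ks), ", chosen_k = ", x$chosen_k,
      " (", x$method, if (x$flat) ", flat curve" else "", ")\n", sep = "")
  invisible(x)
}
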