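#' Cluster-wise hybrid balancing (K-means + per-cluster SMOTE + editing)
#'
#' The package's core procedure. The training table is standardized
#' internally (fit on itself; labels excluded from the geometry), the
#' cluster count is chosen by an SSD elbow scan, the rows are partitioned by
#' K-means, and within each cluster SMOTE raises the cluster-local minority
#' to the cluster-local majority count. An edited-nearest-neighbour pass
#' (`editor = "enn"`, 3 neighbours, or `"knn"`, 5 neighbours) then removes
#' rows whose label disagrees with their neighbourhood — per cluster under
#' the default `scope = "per_cluster"`, or once on the merged table under
#' `scope = "global"`. The merged result is returned on the original
#' feature scale (interpolation commutes with the per-column affine
#' standardization, so synthetic rows are exact in either scale).
#'
#' Clusters with fewer than 2 minority rows, or with no majority rows, are
#' passed through unmodified. Only a training table may be supplied; the
#' held-out test data never enters.
#'
#' @param train Training [labeled_table()] with both classes present.
#' @param editor `"enn"` (3-neighbour cleaning) or `"knn"` (5-neighbour).
#' @param cfg A [resample_config()]; its seed drives every random draw.
#' @param k_max Largest cluster count scanned by the elbow (default 10).
#' @param scope `"per_cluster"` (default) or `"global"` editing.
#' @param restarts Elbow-scan restarts per `k`.
#' @return An object of class `cluster_balance_result`: list with
#'   * `table` — the balanced [labeled_table()];
#'   * `report` — a `balance_report` holding per-cluster and global
#'     pre/post class counts, the editing removal count, `chosen_k`, the
#'     seeds, a `balanced` flag (global class ratio within `[1/1.25, 1.25]`),
#'     and the cluster `assignments` of the input rows;
#'   * `provenance` — one row per surviving synthetic sample: its cluster
#'     and the base/neighbour input row indices and `lambda` that generated
#'     it.
#' @export
cluster_balance <- function(train, editor = c("enn", "knn"),
                            cfg = resample_config(), k_max = 10L,
                            scope = c("per_cluster", "global"),
                            restarts = 5L) {
  editor <- match.arg(editor)
  scope <- match.arg(scope)
  if (any(class_counts(train) == 0L)) {
    stop_kmsmote("training table must contain both classes")
  }
  edit_k <- cfg$k_neighbors2 %||% if (editor == "enn") 3L else 5L
  std <- standardize(train)
  Xs <- std$train$X
  scan <- elbow_k(Xs, k_max = k_max, seed = derive_seed(cfg$seed, 1L),
                  restarts = restarts)
  km <- kmeans_fit(Xs, scan$chosen_k, seed = derive_seed(cfg$seed, 2L))

  pre_counts <- list()
  post_counts <- list()
  pieces_X <- list()
  pieces_y <- list()
  pieces_cl <- list()
  pieces_syn <- list()
  prov <- list()
  n_after_smote <- 0L
  for (i in seq_len(scan$chosen_k)) {
    rows <- which(km$assignments == i)
    sub_std <- subset_rows(std$train, rows)
    sub_orig <- subset_rows(train, rows)
    cc <- class_counts(sub_std)
    pre_counts[[i]] <- cc
    mc <- minority_class(sub_std)
    n_min <- cc[[as.character(mc)]]
    n_maj <- nrow(sub_std$X) - n_min
    if (n_min >= 2L && n_maj > n_min) {
      aug_std <- smote(sub_std, resample_config(
        k_neighbors1 = cfg$k_neighbors1, k_neighbors2 = cfg$k_neighbors2,
        seed = derive_seed(cfg$seed, 10L + i)))
      pairs <- attr(aug_std, "smote_pairs")
      # reconstruct the synthetic rows on the original scale with the same
      # (base, neighbour, lambda) draws
      Xb <- train$X[rows[pairs$base], , drop = FALSE]
      Xn <- train$X[rows[pairs$neighbor], , drop = FALSE]
      aug_X <- rbind(sub_orig$X, Xb + pairs$lambda * (Xn - Xb))
      aug_y <- aug_std$y
      prov_i <- data.frame(cluster = i, base = rows[pairs$base],
                           neighbor = rows[pairs$neighbor],
                           lambda = pairs$lambda)
    } else {
      aug_std <- sub_std
      aug_X <- sub_orig$X
      aug_y <- sub_orig$y
      prov_i <- NULL
    }
    n_after_smote <- n_after_smote + length(aug_y)
    if (scope == "per_cluster" && length(aug_y) > edit_k &&
        length(unique(aug_y)) > 1L) {
      kept <- attr(edit_nn(labeled_table(aug_std$X, aug_y, train$schema),
                           edit_k), "kept")
    } else {
      kept <- seq_along(aug_y)
    }
    n_orig <- nrow(sub_orig$X)
    n_syn_i <- length(aug_y) - n_orig
    kept_syn <- kept[kept > n_orig] - n_orig
    pieces_X[[i]] <- aug_X[kept, , drop = FALSE]
    pieces_y[[i]] <- aug_y[kept]
    pieces_cl[[i]] <- rep(i, length(kept))
    prov[[i]] <- if (!is.null(prov_i)) prov_i[kept_syn, , drop = FALSE]
    # per-output-row index into this cluster's provenance rows (0 = original)
    syn_of <- integer(length(aug_y))
    if (n_syn_i > 0L) syn_of[n_orig + seq_len(n_syn_i)] <- seq_len(n_syn_i)
    pieces_syn[[i]] <- syn_of[kept]
    post_counts[[i]] <- c("0" = sum(aug_y[kept] == 0L),
                          "1" = sum(aug_y[kept] == 1L))
  }
  out <- labeled_table(do.call(rbind, pieces_X), unlist(pieces_y),
                       train$schema)
  provenance <- do.call(rbind, prov[!vapply(prov, is.null, logical(1))])
  out_cluster <- unlist(pieces_cl)
  # global provenance-row id per output row (0 = original row)
  syn_id <- unlist(lapply(seq_along(pieces_syn), function(i) {
    offset <- if (i > 1L) sum(vapply(prov[seq_len(i - 1L)],
                                     function(p) if (is.null(p)) 0L
                                                 else nrow(p), integer(1)))
              else 0L
    ifelse(pieces_syn[[i]] > 0L, pieces_syn[[i]] + offset, 0L)
  }))

  if (scope == "global") {
    out_std_X <- sweep(sweep(out$X, 2, std$center, "-"), 2, std$scale, "/")
    kept <- attr(edit_nn(labeled_table(out_std_X, out$y, train$schema),
                         edit_k), "kept")
    out <- subset_rows(out, kept)
    out_cluster <- out_cluster[kept]
    kept_prov <- syn_id[kept]
    if (!is.null(provenance)) {
      provenance <- provenance[kept_prov[kept_prov > 0L], , drop = FALSE]
    }
    post_counts <- lapply(seq_len(scan$chosen_k), function(i) {
      yy <- out$y[out_cluster == i]
      c("0" = sum(yy == 0L), "1" = sum(yy == 1L))
    })
  }

  global_pre <- class_counts(train)
  global_post <- class_counts(out)
  ratio <- max(global_post) / max(1L, min(global_post))
  balanced <- ratio <= 1.25
  if (!balanced) {
    warning("post-balancing class ratio ", format(ratio, digits = 4),
            " exceeds 1.25", call. = FALSE)
  }
  report <- structure(
    list(chosen_k = scan$chosen_k, elbow = scan, editor = editor,
         scope = scope, edit_k = edit_k, seed = cfg$seed,
         assignments = km$assignments,
         per_cluster_pre = do.call(rbind, pre_counts),
         per_cluster_post = do.call(rbind, post_counts),
         global_pre = global_pre, global_post = global_post,
         n_after_smote = n_after_smote,
         removed_by_editing = n_after_smote - nrow(out$X),
         balanced = balanced),
    class = "balance_report"
  )
  structure(list(table = out, report = report, provenance = provenance),
            class = "cluster_balance_result")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("<balance_report> k = ", x$chosen_k, ", editor = ", x$editor,
      " (k2 = ", x$edit_k, ", scope = ", x$scope, ")\n", sep = "")
  cat("  classes ", x$global_pre[["0"]], "/", x$global_pre[["1"]],
      " -> ", x$global_post[["0"]], "/", x$global_post[["1"]],
      "  (", x$removed_by_editing, " removed by editing",
      if (!x$balanced) "; RATIO OUT OF BAND" else "", ")\n", sep = "")
  invisible(x)
}

#' @export
print.cluster_balance_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Serialize a balance report to JSON
#'
#' @param report A `balance_report` from [cluster_balance()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_balance_report <- function(report, path) {
  obj <- list(
    chosen_k = report$chosen_k,
    editor = report$editor, scope = report$scope, edit_k = report$edit_k,
    seed = report$seed,
    ssds = report$elbow$ssds,
    per_cluster_pre = as.data.frame(report$per_cluster_pre),
    per_cluster_post = as.data.frame(report$per_cluster_post),
    global_pre = as.list(report$global_pre),
    global_post = as.list(report$global_post),
    removed_by_editing = report$removed_by_editing,
    balanced = report$balanced
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
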