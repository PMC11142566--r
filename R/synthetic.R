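#' Configuration for the synthetic table generator
#'
#' Describes an imbalanced, clustered, thyroid-panel-like table. The
#' defaults mirror the reference screening data: 6666 majority ("no") and
#' 250 minority ("yes") rows over 21 features — `Age`, five hormone
#' measurements, and 15 binary indicators, one of which (`Unnamed:22`) is
#' emitted entirely empty so [clean()] has a placeholder column to drop.
#'
#' The hormone columns are drawn from an `n_clusters`-component spherical
#' Gaussian mixture (unit within-cluster noise, cluster centres
#' `cluster_separation` apart along distinct hormone axes) so that an elbow
#' scan has planted structure to recover. Minority rows receive additive
#' mean shifts on the hormone columns, largest on the TSH analogue so the
#' most important feature is known by construction. Binary indicators are
#' Bernoulli with class-dependent rates. Optionally a fraction of labels is
#' flipped uniformly at random so edited-nearest-neighbour cleaning has
#' noise to remove.
#'
#' @param n_majority,n_minority Exact class counts before noise flips.
#' @param n_binary_features Number of binary indicators (the last one is
#'   the all-empty placeholder when `null_column` is `TRUE`).
#' @param n_continuous_features Age plus hormone-like columns.
#' @param n_clusters Planted mixture components (default 5).
#' @param cluster_separation Distance between cluster centres in
#'   within-cluster noise units (default 6).
#' @param class_shift Per-hormone-column additive mean shift for minority
#'   rows, decreasing so the first hormone (TSH analogue) dominates.
#' @param binary_rate_majority,binary_rate_minority Bernoulli rates of the
#'   informative binary indicators per class.
#' @param label_noise_frac Fraction of labels flipped uniformly, in
#'   `[0, 0.5)`; default 0.
#' @param null_column Emit the all-empty placeholder column (default TRUE).
#' @param seed Integer seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_majority = 6666L, n_minority = 250L,
                             n_binary_features = 15L,
                             n_continuous_features = 6L,
                             n_clusters = 5L, cluster_separation = 6,
                             class_shift = NULL,
                             binary_rate_majority = 0.15,
                             binary_rate_minority = 0.25,
                             label_noise_frac = 0, seed = 1L,
                             null_column = TRUE) {
  if (n_majority < 0 || n_minority < 0) stop_kmsmote("counts must be >= 0")
  if (label_noise_frac < 0 || label_noise_frac >= 0.5) {
    stop_kmsmote("label_noise_frac must be in [0, 0.5)")
  }
  n <- n_majority + n_minority
  if (n_clusters > n) stop_kmsmote("more clusters than rows")
  if (n_continuous_features < 2L) {
    stop_kmsmote("need Age plus at least one hormone column")
  }
  n_hormone <- n_continuous_features - 1L
  if (is.null(class_shift)) {
    # TSH analogue largest, tapering off; recycled over the hormone columns
    class_shift <- rep_len(c(2.0, 1.2, 1.0, 0.8, 0.6), n_hormone)
  }
  if (length(class_shift) != n_hormone) {
    stop_kmsmote("class_shift must have one entry per hormone column")
  }
  structure(
    list(n_majority = as.integer(n_majority),
         n_minority = as.integer(n_minority),
         n_binary_features = as.integer(n_binary_features),
         n_continuous_features = as.integer(n_continuous_features),
         n_clusters = as.integer(n_clusters),
         cluster_separation = cluster_separation,
         class_shift = class_shift,
         binary_rate_majority = binary_rate_majority,
         binary_rate_minority = binary_rate_minority,
         label_noise_frac = label_noise_frac,
         null_column = null_column,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Feature names: the thyroid-panel layout when the shape matches it,
# generic names otherwise.
generator_schema <- function(cfg) {
  ref <- thyroid_schema()
  n_feat <- cfg$n_binary_features + cfg$n_continuous_features
  if (cfg$n_binary_features == 15L && cfg$n_continuous_features == 6L) {
    return(ref)
  }
  nb <- cfg$n_binary_features
  nc <- cfg$n_continuous_features
  names_bin <- sprintf("indicator_%02d", seq_len(nb))
  names_cont <- c("Age", sprintf("hormone_%02d", seq_len(nc - 1L)))
  feature_schema(c(names_cont[1], names_bin, names_cont[-1]),
                 c("continuous", rep("binary", nb),
                   rep("continuous", nc - 1L)),
                 ref$target_name, ref$positive_label)
}

# Single internal generator so generate_table() and planted_truth() agree.
generate_internal <- function(cfg) {
  schema <- generator_schema(cfg)
  kinds <- schema$feature_kinds
  cont_names <- names(kinds)[kinds == "continuous"]
  bin_names <- names(kinds)[kinds == "binary"]
  hormone_names <- setdiff(cont_names, "Age")
  null_name <- if (cfg$null_column) {
    if ("Unnamed:22" %in% bin_names) "Unnamed:22"
    else bin_names[length(bin_names)]
  } else character(0)
  info_bin <- setdiff(bin_names, null_name)
  n <- cfg$n_majority + cfg$n_minority
  with_seed(cfg$seed, {
    y_true <- sample(rep(c(0L, 1L), c(cfg$n_majority, cfg$n_minority)))
    z <- sample.int(cfg$n_clusters, n, replace = TRUE)
    # cluster centres: separation/sqrt(2) along distinct hormone axes gives
    # pairwise centre distance == cluster_separation
    d_h <- length(hormone_names)
    centers <- matrix(0, cfg$n_clusters, d_h)
    for (j in seq_len(cfg$n_clusters)) {
      ax <- (j - 1L) %% d_h + 1L
      centers[j, ax] <- cfg$cluster_separation / sqrt(2) * ceiling(j / d_h)
    }
    X <- matrix(NA_real_, n, length(schema$feature_names),
                dimnames = list(NULL, schema$feature_names))
    X[, "Age"] <- stats::rnorm(n)
    H <- centers[z, , drop = FALSE] + matrix(stats::rnorm(n * d_h), n, d_h)
    H <- H + outer(y_true, cfg$class_shift)
    X[, hormone_names] <- H
    rate_sex <- c(0.5, 0.6)   # Sex indicator stays near-balanced per class
    for (nm in info_bin) {
      rates <- if (nm == "Sex") rate_sex
               else c(cfg$binary_rate_majority, cfg$binary_rate_minority)
      X[, nm] <- stats::rbinom(n, 1L, rates[y_true + 1L])
    }
    flipped <- integer(0)
    y <- y_true
    if (cfg$label_noise_frac > 0) {
      flipped <- sample.int(n, round(cfg$label_noise_frac * n))
      y[flipped] <- 1L - y[flipped]
    }
    list(table = labeled_table(X, y, schema),
         clusters = z, y_true = y_true, flipped = sort(flipped),
         importance_order = c(
           hormone_names[order(-cfg$class_shift, seq_along(cfg$class_shift))],
           info_bin, "Age", null_name))
  })
}

#' Generate a synthetic imbalanced clustered table
#'
#' @param cfg A [generator_config()].
#' @return A [labeled_table()] with exactly
#'   `cfg$n_majority + cfg$n_minority` rows; class counts are exact before
#'   label-noise flips. Run [clean()] to drop the placeholder column before
#'   distance-based processing.
#' @export
generate_table <- function(cfg = generator_config()) {
  generate_internal(cfg)$table
}

#' Latent structure planted by the generator
#'
#' Returns the generating truth for parameter-recovery tests: the cluster
#' assignment of every row, the labels before noise flips, the indices of
#' flipped rows, and the planted feature-importance order (hormone columns
#' by descending class shift, ahead of the weakly informative indicators
#' and the uninformative `Age`).
#'
#' @param cfg A [generator_config()].
#' @return List with `clusters`, `y_true`, `flipped`, `importance_order`.
#' @export
planted_truth <- function(cfg = generator_config()) {
  generate_internal(cfg)[c("clusters", "y_true", "flipped",
                           "importance_order")]
}

#' Write the bundled fixtures to a directory
#'
#' Emits the default synthetic table as CSV with its JSON schema sidecar,
#' plus copies of the expert-panel fixture CSVs.
#'
#' @param outdir Output directory (created if missing).
#' @param cfg A [generator_config()] for the synthetic table.
#' @return Character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(outdir, cfg = generator_config()) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_kmsmote("cannot create directory ", outdir)
  }
  tab <- generate_table(cfg)
  paths <- c(
    file.path(outdir, "synthetic_thyroid.csv"),
    file.path(outdir, "synthetic_thyroid.schema.json"),
    file.path(outdir, "expert_interviews.csv"),
    file.path(outdir, "expert_survey.csv"),
    file.path(outdir, "importance_levels.csv")
  )
  write_csv(tab, paths[1])
  write_schema(tab$schema, paths[2])
  for (f in paths[3:5]) {
    file.copy(system.file("extdata", basename(f), package = "kmsmote"), f,
              overwrite = TRUE)
  }
  invisible(paths)
}
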