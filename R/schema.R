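#' Feature schema for a labeled table
#'
#' A schema names the feature columns of a binary-classification table, tags
#' each one as `"binary"` (0/1 indicator) or `"continuous"`, and identifies
#' the target column together with the category that maps to class 1.
#'
#' @param feature_names Character vector of unique feature column names.
#' @param feature_kinds Character vector, same length, each `"binary"` or
#'   `"continuous"`.
#' @param target_name Name of the target column; must not be a feature.
#' @param positive_label Value of the target column coded as 1 (the minority
#'   "case" class in the reference data).
#'
#' @return An object of class `feature_schema`.
#' @seealso [thyroid_schema()] for the 21-feature thyroid-panel reference
#'   layout.
#' @export
feature_schema <- function(feature_names, feature_kinds, target_name,
                           positive_label = "yes") {
  feature_names <- as.character(feature_names)
  feature_kinds <- as.character(feature_kinds)
  if (anyDuplicated(feature_names)) {
    stop_kmsmote("feature names must be unique")
  }
  if (length(feature_kinds) != length(feature_names)) {
    stop_kmsmote("feature_kinds must match feature_names in length")
  }
  if (!all(feature_kinds %in% c("binary", "continuous"))) {
    stop_kmsmote("feature kinds must be 'binary' or 'continuous'")
  }
  if (target_name %in% feature_names) {
    stop_kmsmote("target column '", target_name, "' must not be a feature")
  }
  structure(
    list(
      feature_names = feature_names,
      feature_kinds = stats::setNames(feature_kinds, feature_names),
      target_name = as.character(target_name),
      positive_label = positive_label
    ),
    class = "feature_schema"
  )
}

#' Thyroid-panel reference schema
#'
#' The 21-feature layout of the UCI-derived thyroid screening table: 15
#' binary indicators (including the always-empty `Unnamed:22` column, which
#' [clean()] drops), `Age`, and five hormone-panel measurements
#' (`TSH`, `T3_measured`, `TT4_measured`, `T4U_measured`, `FTI_measured`).
#' The target is `Outlier_label` with `"yes"` (disease) coded as class 1.
#'
#' @return A [feature_schema()].
#' @export
thyroid_schema <- function() {
  feats <- c(
    Age = "continuous",
    Sex = "binary",
    on_thyroxine = "binary",
    query_on_thyroxine = "binary",
    on_antithyroid_medication = "binary",
    sick = "binary",
    Pregnant = "binary",
    thyroid_surgery = "binary",
    I131_treatment = "binary",
    query_hypothyroid = "binary",
    query_hyperthyroid = "binary",
    lithium = "binary",
    goitre = "binary",
    tumor = "binary",
    `Unnamed:22` = "binary",
    psych = "binary",
    TSH = "continuous",
    T3_measured = "continuous",
    TT4_measured = "continuous",
    T4U_measured = "continuous",
    FTI_measured = "continuous"
  )
  feature_schema(names(feats), unname(feats), "Outlier_label", "yes")
}

#' Read / write a schema sidecar (JSON)
#'
#' The sidecar is a small JSON object
#' `{features: [{name, kind}, ...], target, positive_label}` accompanying a
#' CSV table.
#'
#' @param path File path of the JSON sidecar.
#' @return `read_schema()` returns a [feature_schema()];
#'   `write_schema()` returns `path` invisibly.
#' @export
read_schema <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  feature_schema(obj$features$name, obj$features$kind, obj$target,
                 obj$positive_label)
}

#' @rdname read_schema
#' @param schema A [feature_schema()].
#' @export
write_schema <- function(schema, path) {
  obj <- list(
    features = data.frame(name = schema$feature_names,
                          kind = unname(schema$feature_kinds)),
    target = schema$target_name,
    positive_label = schema$positive_label
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("<feature_schema> ", length(x$feature_names), " features (",
      sum(x$feature_kinds == "binary"), " binary, ",
      sum(x$feature_kinds == "continuous"), " continuous), target '",
      x$target_name, "' (positive = '", x$positive_label, "')\n", sep = "")
  invisible(x)
}
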