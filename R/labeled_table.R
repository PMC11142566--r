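#' Labeled binary-classification table
#'
#' The universal container passed between every stage: a numeric feature
#' matrix `X`, a 0/1 label vector `y` (1 = positive / minority "case" class),
#' and the [feature_schema()] describing the columns.
#'
#' @param X Numeric matrix (rows = patients, columns = features). Missing
#'   values are permitted until [clean()] has run.
#' @param y Integer or numeric vector of labels in `{0, 1}` (NA allowed
#'   pre-cleaning).
#' @param schema A [feature_schema()]; inferred from column names/values if
#'   omitted.
#'
#' @return An object of class `labeled_table` with elements `X`, `y`,
#'   `schema`.
#' @export
labeled_table <- function(X, y, schema = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  if (nrow(X) != length(y)) {
    stop_kmsmote("X and y disagree on the number of rows")
  }
  if (!all(y %in% c(0L, 1L) | is.na(y))) {
    stop_kmsmote("labels must be 0/1 (or NA before cleaning)")
  }
  if (is.null(schema)) schema <- infer_schema(X)
  if (!identical(colnames(X), schema$feature_names)) {
    if (is.null(colnames(X))) {
      colnames(X) <- schema$feature_names
    } else if (setequal(colnames(X), schema$feature_names)) {
      X <- X[, schema$feature_names, drop = FALSE]
    } else {
      stop_kmsmote("columns of X do not match the schema")
    }
  }
  structure(list(X = X, y = y, schema = schema), class = "labeled_table")
}

infer_schema <- function(X, target_name = "Outlier_label",
                         positive_label = "yes") {
  nm <- colnames(X) %||% sprintf("V%d", seq_len(ncol(X)))
  kinds <- apply(X, 2, function(col) {
    v <- unique(col[!is.na(col)])
    if (length(v) > 0 && all(v %in% c(0, 1))) "binary" else "continuous"
  })
  feature_schema(nm, kinds, target_name, positive_label)
}

#' Class counts of a labeled table
#'
#' @param table A [labeled_table()].
#' @return Named integer vector `c("0" = n0, "1" = n1)`.
#' @export
class_counts <- function(table) {
  c("0" = sum(table$y == 0L, na.rm = TRUE),
    "1" = sum(table$y == 1L, na.rm = TRUE))
}

#' @export
print.labeled_table <- function(x, ...) {
  cc <- class_counts(x)
  cat("<labeled_table> ", nrow(x$X), " rows x ", ncol(x$X), " features; ",
      "class 0: ", cc[["0"]], ", class 1: ", cc[["1"]], "\n", sep = "")
  invisible(x)
}

#' @export
dim.labeled_table <- function(x) dim(x$X)

# Row subset, preserving schema and attributes we care about.
subset_rows <- function(table, idx) {
  labeled_table(table$X[idx, , drop = FALSE], table$y[idx], table$schema)
}

#' Read a labeled table from CSV
#'
#' Expects an RFC-4180 CSV with a header row. Binary-coded feature columns
#' are parsed as 0/1 reals; the target column is mapped to 1 where it equals
#' the schema's `positive_label` (case-insensitively for strings) and 0
#' otherwise. Row order is preserved.
#'
#' @param path CSV file path.
#' @param schema Optional [feature_schema()]; inferred from the file when
#'   omitted (the target column is then `target` below).
#' @param target Target column name used when `schema` is omitted.
#' @param positive_label Positive category used when `schema` is omitted.
#' @return A [labeled_table()].
#' @export
load_csv <- function(path, schema = NULL, target = "Outlier_label",
                     positive_label = "yes") {
  if (!file.exists(path)) stop_kmsmote("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  tname <- if (!is.null(schema)) schema$target_name else target
  if (!tname %in% names(df)) {
    stop_kmsmote("target column '", tname, "' missing from ", path)
  }
  pos <- if (!is.null(schema)) schema$positive_label else positive_label
  ycol <- df[[tname]]
  y <- if (is.character(ycol)) {
    ifelse(is.na(ycol) | ycol == "", NA_integer_,
           as.integer(tolower(ycol) == tolower(as.character(pos))))
  } else {
    as.integer(ycol == pos | ycol == 1)
  }
  feat <- df[setdiff(names(df), tname)]
  if (!is.null(schema)) {
    missing_cols <- setdiff(schema$feature_names, names(feat))
    if (length(missing_cols)) {
      stop_kmsmote("feature columns missing from ", path, ": ",
                   paste(missing_cols, collapse = ", "))
    }
    feat <- feat[schema$feature_names]
  }
  X <- matrix(NA_real_, nrow(df), length(feat),
              dimnames = list(NULL, names(feat)))
  for (j in seq_along(feat)) {
    col <- feat[[j]]
    if (is.character(col)) {
      bad <- which(!is.na(col) & col != "" &
                     is.na(suppressWarnings(as.numeric(col))))
      if (length(bad)) {
        stop_kmsmote("non-numeric value '", col[bad[1]], "' at row ", bad[1],
                     ", column '", names(feat)[j], "'")
      }
      col[col == ""] <- NA
      col <- as.numeric(col)
    }
    X[, j] <- as.numeric(col)
  }
  labeled_table(X, y, schema)
}

#' Write a labeled table to CSV
#'
#' Feature values are written with 17 significant digits so that a
#' [load_csv()] round trip restores `X` and `y` bit-for-bit. The target is
#' written as the schema's positive label / `"no"` strings.
#'
#' @param table A [labeled_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_csv <- function(table, path) {
  fmt <- function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- ""
    out
  }
  cols <- c(
    lapply(seq_len(ncol(table$X)), function(j) fmt(table$X[, j])),
    list(ifelse(is.na(table$y), "",
                ifelse(table$y == 1L, as.character(table$schema$positive_label),
                       "no")))
  )
  header <- c(colnames(table$X), table$schema$target_name)
  quote_field <- function(x) {
    need <- grepl('[",\n]', x)
    x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
    x
  }
  lines <- c(
    paste(quote_field(header), collapse = ","),
    do.call(paste, c(lapply(cols, quote_field), sep = ","))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Clean a labeled table
#'
#' Mirrors a conventional preprocessing pass on screening tables: columns
#' that are entirely missing (such as the reference layout's `Unnamed:22`
#' placeholder) are dropped, rows with a missing target are dropped, and the
#' remaining missing feature cells are imputed by the column median
#' (continuous) or mode (binary). Optionally winsorizes continuous columns.
#'
#' @param table A [labeled_table()].
#' @param winsorize `NULL` (default, off) or a length-2 numeric of lower and
#'   upper quantiles at which continuous columns are clipped.
#' @return A cleaned [labeled_table()] with no missing values.
#' @export
clean <- function(table, winsorize = NULL) {
  X <- table$X
  y <- table$y
  schema <- table$schema
  keep_col <- colSums(!is.na(X)) > 0
  if (!all(keep_col)) {
    X <- X[, keep_col, drop = FALSE]
    schema <- feature_schema(schema$feature_names[keep_col],
                             unname(schema$feature_kinds[keep_col]),
                             schema$target_name, schema$positive_label)
  }
  keep_row <- !is.na(y)
  X <- X[keep_row, , drop = FALSE]
  y <- y[keep_row]
  if (nrow(X) == 0L) stop_kmsmote("cleaning removed every row")
  kinds <- schema$feature_kinds[colnames(X)]
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) {
      obs <- X[!miss, j]
      X[miss, j] <- if (kinds[j] == "binary") {
        as.numeric(names(which.max(table(obs))))
      } else {
        stats::median(obs)
      }
    }
  }
  if (!is.null(winsorize)) {
    stopifnot(length(winsorize) == 2, winsorize[1] < winsorize[2])
    for (j in which(kinds == "continuous")) {
      q <- stats::quantile(X[, j], winsorize, names = FALSE)
      X[, j] <- pmin(pmax(X[, j], q[1]), q[2])
    }
  }
  labeled_table(X, y, schema)
}

#' Standardize features, fitting on the training table only
#'
#' Continuous columns are z-scored with the training mean and the population
#' standard deviation (denominator `n`); binary columns pass through
#' untouched; a zero-variance column gets scale 1 so its values become 0.
#' The location/scale are fitted on `train` alone and then applied to any
#' additional tables, so no statistic ever leaks from held-out data.
#'
#' @param train A [labeled_table()] used to fit location and scale.
#' @param ... Further `labeled_table`s to transform with the same fit.
#' @return A list with `train`, `extra` (list of the transformed `...`
#'   tables), and the named `center`/`scale` vectors (features that pass
#'   through have center 0 and scale 1).
#' @export
standardize <- function(train, ...) {
  extra <- list(...)
  kinds <- train$schema$feature_kinds[colnames(train$X)]
  center <- stats::setNames(numeric(ncol(train$X)), colnames(train$X))
  scale <- stats::setNames(rep(1, ncol(train$X)), colnames(train$X))
  for (j in which(kinds == "continuous")) {
    v <- train$X[, j]
    center[j] <- mean(v)
    s <- sqrt(mean((v - center[j])^2))
    scale[j] <- if (s > 0) s else 1
  }
  tf <- function(tab) {
    X <- sweep(sweep(tab$X, 2, center, "-"), 2, scale, "/")
    labeled_table(X, tab$y, tab$schema)
  }
  list(train = tf(train), extra = lapply(extra, tf),
       center = center, scale = scale)
}

#' Split a table into train and test partitions
#'
#' The train size is `floor(ratio * n)` with the remainder going to test;
#' with `n = 6916` and the default ratio this yields the reference 5532/1384
#' partition. The permutation is driven solely by `seed`. Stratified mode
#' applies the same rule to each class independently.
#'
#' @param table A [labeled_table()].
#' @param ratio Train fraction in (0, 1); default 0.8.
#' @param seed Integer seed for the row permutation.
#' @param stratified Split each class independently (default `FALSE`).
#' @return An object of class `split_pair`: list with `train`, `test`,
#'   `ratio`, `seed`, `stratified`, and the row index vectors `train_idx`,
#'   `test_idx`.
#' @export
split_table <- function(table, ratio = 0.8, seed = 1L, stratified = FALSE) {
  if (!(ratio > 0 && ratio < 1)) stop_kmsmote("ratio must be in (0, 1)")
  n <- nrow(table$X)
  train_idx <- with_seed(seed, {
    if (!stratified) {
      sample.int(n)[seq_len(floor(ratio * n))]
    } else {
      unlist(lapply(c(0L, 1L), function(cl) {
        rows <- which(table$y == cl)
        rows[sample.int(length(rows))][seq_len(floor(ratio * length(rows)))]
      }), use.names = FALSE)
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  train <- subset_rows(table, train_idx)
  test <- subset_rows(table, test_idx)
  for (part in list(train, test)) {
    if (any(class_counts(part) == 0L)) {
      warning("a class is absent from one side of the split", call. = FALSE)
      break
    }
  }
  structure(
    list(train = train, test = test, ratio = ratio, seed = seed,
         stratified = stratified, train_idx = train_idx, test_idx = test_idx),
    class = "split_pair"
  )
}

#' @export
print.split_pair <- function(x, ...) {
  cat("<split_pair> train ", nrow(x$train$X), " rows / test ",
      nrow(x$test$X), " rows (ratio ", x$ratio,
      if (x$stratified) ", stratified" else "", ")\n", sep = "")
  invisible(x)
}
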