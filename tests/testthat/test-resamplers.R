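test_that("knn_query handles toy cases and the deterministic tie rule", {
  X <- matrix(c(0, 1, 3), ncol = 1)
  nn <- knn_query(X, k = 1, exclude_self = TRUE)
  expect_equal(nn$idx[1, 1], 2L)
  # two equidistant candidates: lower row index wins
  X2 <- matrix(c(0, 1, -1), ncol = 1)
  nn2 <- knn_query(X2, matrix(0), k = 2)
  expect_equal(nn2$idx[1, ], c(1L, 2L))
  expect_error(knn_query(X, k = 3, exclude_self = TRUE), "available")
})

test_that("knn_query matches the exhaustive-scan oracle on random data", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(50 * 3), 50, 3)
    got <- knn_query(X, k = 5, exclude_self = TRUE)
    expect_identical(got$idx, oracle_knn(X, X, 5, exclude_self = TRUE))
    Q <- matrix(rnorm(10 * 3), 10, 3)
    got_q <- knn_query(X, Q, k = 4)
    expect_identical(got_q$idx, oracle_knn(X, Q, 4))
    expect_equal(got_q$dist[, 1],
                 vapply(seq_len(10), function(i) {
                   min(oracle_dist(X, Q[i, ]))
                 }, numeric(1)))
  }
})

test_that("smote equalizes class counts and preserves original rows", {
  tab <- random_table(120, p1 = 0.15, seed = 6)
  out <- smote(tab, resample_config(seed = 6))
  cc <- class_counts(out)
  expect_equal(cc[["1"]], cc[["0"]])
  expect_identical(out$X[seq_len(120), ], tab$X)    # originals verbatim
  expect_identical(out$y[seq_len(120)], tab$y)
})

test_that("smote synthetics lie on within-class minority segments", {
  tab <- random_table(80, p1 = 0.2, seed = 8)
  out <- smote(tab, resample_config(seed = 8))
  pairs <- attr(out, "smote_pairs")
  n <- nrow(tab$X)
  syn <- out$X[(n + 1):nrow(out$X), , drop = FALSE]
  expect_true(all(tab$y[pairs$base] == 1L))
  expect_true(all(tab$y[pairs$neighbor] == 1L))
  recon <- tab$X[pairs$base, ] +
    pairs$lambda * (tab$X[pairs$neighbor, ] - tab$X[pairs$base, ])
  expect_equal(syn, recon, ignore_attr = TRUE)
  expect_true(all(pairs$lambda >= 0 & pairs$lambda < 1))
})

test_that("smote two-point minority interpolates the only neighbour pair", {
  X <- rbind(c(0, 0), c(1, 1), c(10, 0), c(11, 1), c(12, 0), c(13, 1))
  colnames(X) <- c("a", "b")
  tab <- labeled_table(X, c(1L, 1L, 0L, 0L, 0L, 0L))
  out <- smote(tab, resample_config(k_neighbors1 = 1, seed = 2))
  syn <- out$X[7:8, , drop = FALSE]
  expect_equal(syn[, 1], syn[, 2])                 # on the diagonal segment
  expect_true(all(syn >= 0 & syn < 1))
})

test_that("smote degenerate inputs behave per contract", {
  tab <- random_table(40, p1 = 0.5, seed = 3)
  cc <- class_counts(tab)
  if (cc[["1"]] == cc[["0"]]) {
    expect_identical(smote(tab), tab)
  }
  one_min <- labeled_table(matrix(rnorm(10), 5, 2), c(0L, 0L, 0L, 0L, 1L))
  expect_error(smote(one_min), "cannot interpolate")
})

test_that("smote is deterministic under its seed", {
  tab <- random_table(100, p1 = 0.2, seed = 10)
  a <- smote(tab, resample_config(seed = 42))
  b <- smote(tab, resample_config(seed = 42))
  expect_identical(a$X, b$X)
  c <- smote(tab, resample_config(seed = 43))
  expect_false(identical(a$X, c$X))
})

test_that("enn_clean removes the planted noise point in the 1-D toy", {
  tab <- line_table(c(0, 1, 2, 10, 1.5), c(0L, 0L, 0L, 0L, 1L))
  expect_warning(out <- enn_clean(tab), "emptied")
  expect_identical(attr(out, "kept"), 1:4)
  expect_true(all(out$y == 0L))
})

test_that("knn_clean with 5 neighbours matches the hand vote on 6 points", {
  tab <- line_table(c(0, 1, 2, 3, 10, 1.5), c(0L, 0L, 0L, 0L, 0L, 1L))
  expect_warning(out <- knn_clean(tab), "emptied")
  expect_identical(attr(out, "kept"), 1:5)
})

test_that("editing is anti-extensive, label-symmetric, single-class safe", {
  single <- line_table(c(1, 2, 3, 4, 5), rep(1L, 5))
  expect_identical(enn_clean(single)$X, single$X)
  tab <- random_table(100, p1 = 0.4, seed = 12)
  out <- enn_clean(tab)
  kept <- attr(out, "kept")
  expect_true(all(kept %in% seq_len(100)))
  expect_identical(out$X, tab$X[kept, , drop = FALSE])
  # identical data and k give identical results through either editor entry
  cfg3 <- resample_config(k_neighbors2 = 3)
  expect_identical(enn_clean(tab, cfg3)$X, knn_clean(tab, cfg3)$X)
})

test_that("editing matches the brute-force oracle on random instances", {
  for (seed in 1:6) {
    tab <- random_table(60 + 10 * seed, p1 = 0.3, seed = 100 + seed)
    expect_identical(attr(suppressWarnings(enn_clean(tab)), "kept"),
                     oracle_edit(tab$X, tab$y, 3L))
    expect_identical(attr(suppressWarnings(knn_clean(tab)), "kept"),
                     oracle_edit(tab$X, tab$y, 5L))
  }
})

test_that("editing ties keep the row (even k, split vote)", {
  # rows 1 and 3 see one neighbour of each label: a tied vote keeps them;
  # row 2 sees two opposite-label neighbours and is deleted
  tab <- line_table(c(0, 0.1, 0.2), c(0L, 1L, 0L))
  expect_warning(out <- enn_clean(tab, resample_config(k_neighbors2 = 2)),
                 "emptied")
  expect_identical(attr(out, "kept"), c(1L, 3L))
})

test_that("nearmiss keeps the closest majority rows, minority untouched", {
  tab <- random_table(60, p1 = 0.25, seed = 14)
  out <- nearmiss(tab)
  cc <- class_counts(out)
  expect_equal(cc[["0"]], cc[["1"]])
  keep_oracle <- oracle_nearmiss(tab$X, tab$y)
  expect_identical(out$X, tab$X[keep_oracle, , drop = FALSE])
  # balanced input is returned unchanged
  bal <- random_table(40, p1 = 0.5, seed = 15)
  if (length(unique(class_counts(bal))) == 1L) {
    expect_identical(nearmiss(bal), bal)
  }
})

test_that("hybrid resamplers equal their manual two-step composition", {
  tab <- random_table(90, p1 = 0.2, seed = 16)
  cfg <- resample_config(seed = 7)
  expect_identical(smote_enn(tab, cfg)$X, enn_clean(smote(tab, cfg), cfg)$X)
  expect_identical(smote_knn(tab, cfg)$X, knn_clean(smote(tab, cfg), cfg)$X)
})

test_that("hybrids shrink both classes below post-SMOTE counts on noisy data", {
  tab <- clean(generate_table(small_config(seed = 18,
                                           label_noise_frac = 0.1)))
  std <- standardize(tab)
  cfg <- resample_config(seed = 18)
  after_smote <- class_counts(smote(std$train, cfg))
  for (fun in list(smote_enn, smote_knn)) {
    cc <- class_counts(fun(std$train, cfg))
    expect_lt(cc[["0"]], after_smote[["0"]])
    expect_lt(cc[["1"]], after_smote[["1"]])
  }
})

test_that("well-separated clean data loses almost nothing to editing", {
  set.seed(20)
  X <- rbind(matrix(rnorm(100, 0, 0.1), 50, 2),
             matrix(rnorm(100, 5, 0.1), 50, 2))
  tab <- labeled_table(X, rep(c(0L, 1L), each = 50))
  out <- smote_enn(tab, resample_config(seed = 20))
  expect_equal(unname(class_counts(out)), c(50L, 50L))
})
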