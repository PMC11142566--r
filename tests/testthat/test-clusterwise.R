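test_that("kmeans closed forms: k = 1 and hand geometry at k = 2", {
  set.seed(1)
  X <- matrix(rnorm(60), 20, 3)
  km1 <- kmeans_fit(X, 1, seed = 1)
  expect_equal(km1$centroids[1, ], colMeans(X), ignore_attr = TRUE)
  expect_equal(km1$ssd, sum(sweep(X, 2, colMeans(X))^2))

  X2 <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  km2 <- kmeans_fit(X2, 2, seed = 5)
  cents <- km2$centroids[order(km2$centroids[, 1]), ]
  expect_equal(cents, rbind(c(0, 0.5), c(10, 0.5)), ignore_attr = TRUE)
  expect_equal(km2$ssd, 1.0)
  expect_error(kmeans_fit(X2, 5, seed = 1), "exceeds")
})

test_that("reported ssd is internally consistent and near stats::kmeans", {
  set.seed(2)
  X <- matrix(rnorm(300), 100, 3)
  km <- kmeans_fit(X, 4, seed = 7)
  recomputed <- sum((X - km$centroids[km$assignments, ])^2)
  expect_equal(km$ssd, recomputed)
  # independent route: best of several stats::kmeans runs agrees closely
  ref <- min(vapply(1:5, function(s) {
    set.seed(s)
    stats::kmeans(X, 4, nstart = 5)$tot.withinss
  }, numeric(1)))
  best <- min(vapply(1:5, function(s) kmeans_fit(X, 4, seed = s)$ssd,
                     numeric(1)))
  expect_lt(abs(best - ref) / ref, 0.05)
})

test_that("kmeans is deterministic under seed", {
  set.seed(3)
  X <- matrix(rnorm(200), 50, 4)
  a <- kmeans_fit(X, 3, seed = 11)
  b <- kmeans_fit(X, 3, seed = 11)
  expect_identical(a$centroids, b$centroids)
  expect_identical(a$assignments, b$assignments)
})

test_that("elbow scan: ssd nonincreasing and planted k recovered", {
  tab <- clean(generate_table(small_config(seed = 23)))
  X <- standardize(tab)$train$X
  scan <- elbow_k(X, k_max = 8, seed = 23, restarts = 5)
  expect_true(all(diff(scan$ssds) <= 1e-8))
  expect_equal(scan$chosen_k, 5L)
  expect_true(scan$chosen_k >= 2 && scan$chosen_k <= 7)
})

test_that("elbow warns and flags a degenerate (flat) ssd curve", {
  # all rows identical: ssd is 0 for every k, so the curve carries no elbow
  X <- matrix(1, 20, 2)
  expect_warning(scan <- elbow_k(X, k_max = 4, seed = 31, restarts = 2),
                 "decreasing")
  expect_true(scan$flat)
  expect_true(scan$chosen_k %in% 2:3)
})

test_that("knee-rule alternative picks the planted k too", {
  tab <- clean(generate_table(small_config(seed = 29)))
  X <- standardize(tab)$train$X
  scan <- elbow_k(X, k_max = 8, seed = 29, restarts = 5, method = "knee")
  expect_equal(scan$chosen_k, 5L)
})

test_that("cluster_balance equalizes within tolerance and reports counts", {
  tab <- clean(generate_table(small_config(seed = 41)))
  res <- cluster_balance(tab, "enn", resample_config(seed = 41), k_max = 8)
  cc <- res$report$global_post
  expect_true(max(cc) / min(cc) <= 1.25)
  expect_true(res$report$balanced)
  expect_equal(colSums(res$report$per_cluster_post),
               unname(res$report$global_post), ignore_attr = TRUE)
  expect_equal(nrow(res$table$X), sum(res$report$per_cluster_post))
})

test_that("cluster_balance improves the minority fraction", {
  tab <- clean(generate_table(small_config(seed = 43,
                                           label_noise_frac = 0.05)))
  res <- suppressWarnings(
    cluster_balance(tab, "knn", resample_config(seed = 43), k_max = 8))
  frac_in <- mean(tab$y == 1L)
  frac_out <- mean(res$table$y == 1L)
  expect_gt(frac_out, frac_in)
})

test_that("every synthetic row interpolates two rows of its own cluster", {
  tab <- clean(generate_table(small_config(seed = 47)))
  res <- cluster_balance(tab, "enn", resample_config(seed = 47), k_max = 8)
  prov <- res$provenance
  a <- res$report$assignments
  expect_gt(nrow(prov), 0L)
  expect_true(all(a[prov$base] == prov$cluster))
  expect_true(all(a[prov$neighbor] == prov$cluster))
  # and the surviving synthetic rows are reconstructible from provenance
  n_orig_kept <- nrow(res$table$X) - nrow(prov)
  expect_true(all(prov$lambda >= 0 & prov$lambda < 1))
})

test_that("cluster_balance is a function of the training table alone", {
  tab <- clean(generate_table(small_config(seed = 53)))
  sp <- split_table(tab, 0.8, seed = 53)
  res1 <- cluster_balance(sp$train, "enn", resample_config(seed = 53),
                          k_max = 8)
  # mutate the held-out table; the balancer must not notice
  sp$test$X[] <- sp$test$X * -99
  res2 <- cluster_balance(sp$train, "enn", resample_config(seed = 53),
                          k_max = 8)
  expect_identical(res1$table$X, res2$table$X)
  expect_identical(res1$table$y, res2$table$y)
})

test_that("cluster_balance is deterministic and rejects single-class input", {
  tab <- clean(generate_table(small_config(seed = 59)))
  a <- cluster_balance(tab, "knn", resample_config(seed = 59), k_max = 8)
  b <- cluster_balance(tab, "knn", resample_config(seed = 59), k_max = 8)
  expect_identical(a$table$X, b$table$X)
  single <- labeled_table(matrix(rnorm(20), 10, 2), rep(0L, 10))
  expect_error(cluster_balance(single), "both classes")
})

test_that("global-scope editing runs once on the merged table", {
  tab <- clean(generate_table(small_config(seed = 61,
                                           label_noise_frac = 0.05)))
  res <- suppressWarnings(
    cluster_balance(tab, "enn", resample_config(seed = 61),
                    k_max = 8, scope = "global"))
  expect_equal(res$report$scope, "global")
  expect_lt(nrow(res$table$X), res$report$n_after_smote)
  prov <- res$provenance
  a <- res$report$assignments
  expect_true(all(a[prov$base] == prov$cluster))
})

test_that("balanced well-separated input passes through nearly unchanged", {
  set.seed(67)
  X <- rbind(matrix(rnorm(120, 0, 0.15), 60, 2),
             matrix(rnorm(120, 8, 0.15), 60, 2))
  colnames(X) <- c("a", "b")
  tab <- labeled_table(X, rep(c(0L, 1L), each = 60))
  res <- cluster_balance(tab, "enn", resample_config(seed = 67), k_max = 4,
                         restarts = 3)
  expect_equal(unname(res$report$global_post), unname(class_counts(tab)))
})
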