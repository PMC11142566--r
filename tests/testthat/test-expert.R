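test_that("interview_rank reproduces every printed frequency/rank pair", {
  m <- thyroid_expert_interviews()
  got <- interview_rank(m)
  expected_freq <- c(TSH = 5, T3_measured = 5, on_thyroxine = 4,
                     TT4_measured = 3, Age = 4, T4U_measured = 4, Sex = 4,
                     query_hypothyroid = 3, FTI_measured = 4,
                     I131_treatment = 4, goitre = 4, thyroid_surgery = 1,
                     query_hyperthyroid = 2, tumor = 1, sick = 1,
                     on_antithyroid_medication = 1, psych = 1, lithium = 1,
                     Pregnant = 2, query_on_thyroxine = 2)
  expected_rank <- ifelse(expected_freq == 5, 1L,
                          ifelse(expected_freq >= 3, 2L, 3L))
  expect_equal(stats::setNames(got$frequency, got$feature), expected_freq)
  expect_equal(unname(stats::setNames(got$rank, got$feature)[
    names(expected_freq)]), unname(expected_rank))
  expect_equal(sum(got$rank == 1L), 2L)
  expect_equal(sum(got$rank == 2L), 9L)
  expect_equal(sum(got$rank == 3L), 9L)
})

test_that("interview_rank edge rules and validation", {
  m <- rbind(all5 = c(1, 1, 1, 1, 1), none = c(0, 0, 0, 0, 0))
  got <- interview_rank(m)
  expect_equal(got$rank, c(1L, 3L))
  expect_equal(got$frequency, c(5, 0))
  expect_error(interview_rank(rbind(a = c(2, 0))), "0/1")
})

test_that("survey_score applies 3/2/1 weights with descending serials", {
  sv <- thyroid_expert_survey()
  got <- survey_score(sv)
  score_of <- function(f) got$score[got$feature == f]
  expect_equal(score_of("TSH"), 80)           # 3*23 + 2*4 + 1*3
  expect_equal(score_of("lithium"), 37)       # 3*2 + 2*3 + 1*25
  expect_equal(got$serial[got$feature == "TSH"], 1L)
  # the all-low floor for 30 respondents
  floor_row <- survey_score(data.frame(feature = "f", high = 0, medium = 0,
                                       low = 30))
  expect_equal(floor_row$score, 30)
  expect_warning(
    survey_score(data.frame(feature = c("a", "b"), high = c(1, 1),
                            medium = c(1, 0), low = c(1, 1))),
    "respondent")
})

test_that("tabulations are permutation-equivariant in feature order", {
  sv <- thyroid_expert_survey()
  perm <- rev(seq_len(nrow(sv)))
  a <- survey_score(sv)
  b <- survey_score(sv[perm, ])
  expect_equal(stats::setNames(a$score, a$feature)[b$feature],
               stats::setNames(b$score, b$feature), ignore_attr = TRUE)
  m <- thyroid_expert_interviews()
  ra <- interview_rank(m)
  rb <- interview_rank(m[perm, ])
  expect_equal(stats::setNames(ra$rank, ra$feature)[rb$feature],
               stats::setNames(rb$rank, rb$feature), ignore_attr = TRUE)
})

test_that("assign_levels partitions by rank counts and stays monotone", {
  sv <- survey_score(thyroid_expert_survey())
  lv <- assign_levels(sv, c(2L, 7L, 11L))
  expect_equal(sum(lv$level == "High"), 2L)
  expect_equal(sum(lv$level == "Medium"), 7L)
  expect_equal(sum(lv$level == "Low"), 11L)
  # monotone: higher score never gets a lower level
  num <- c(High = 1L, Medium = 2L, Low = 3L)[as.character(lv$level)]
  ord <- order(-lv$score)
  expect_true(all(diff(num[ord]) >= 0))
  expect_error(assign_levels(sv, c(1L, 1L, 1L)), "level_counts")
  all_high <- assign_levels(sv, c(20L, 0L, 0L))
  expect_true(all(all_high$level == "High"))
})

test_that("assign_levels ties follow serial order; gap rule is available", {
  uni <- importance_ranking(letters[1:6], rep(1, 6))
  lv <- assign_levels(uni, c(2L, 2L, 2L))
  expect_equal(as.character(lv$level),
               c("High", "High", "Medium", "Medium", "Low", "Low"))
  gappy <- importance_ranking(letters[1:6], c(10, 9.5, 5, 4.8, 1, 0.9))
  lg <- assign_levels(gappy, method = "gaps")
  expect_equal(as.character(lg$level),
               c("High", "High", "Medium", "Medium", "Low", "Low"))
})

test_that("alignment on the published level table finds the two mismatches", {
  ref <- thyroid_importance_levels()
  xai <- data.frame(feature = ref$feature, serial = ref$xai_serial,
                    level = ref$xai_level)
  expert <- data.frame(feature = ref$feature, serial = ref$expert_serial,
                       level = ref$expert_level)
  rep <- alignment_report(xai, expert)
  expect_equal(sort(rep$disagreements), c("I131_treatment", "goitre"))
  expect_equal(rep$match_fraction, 18 / 20)
  # symmetric in its arguments
  rep2 <- alignment_report(expert, xai)
  expect_equal(rep2$match_fraction, rep$match_fraction)
  expect_equal(rep2$spearman, rep$spearman)
})

test_that("alignment extremes: identity and reversal", {
  r <- assign_levels(importance_ranking(letters[1:5], 5:1),
                     c(1L, 2L, 2L))
  idem <- alignment_report(r, r)
  expect_equal(idem$match_fraction, 1)
  expect_equal(idem$spearman, 1)
  rev_r <- assign_levels(importance_ranking(letters[1:5], 1:5),
                         c(1L, 2L, 2L))
  opp <- alignment_report(r, rev_r)
  expect_equal(opp$spearman, -1)
  expect_error(alignment_report(r, assign_levels(
    importance_ranking(letters[2:6], 5:1), c(1L, 2L, 2L))), "feature sets")
})

test_that("permutation importance recovers a planted single-feature signal", {
  set.seed(83)
  n <- 400
  X <- cbind(signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  y <- as.integer(X[, "signal"] > 0)
  tab <- labeled_table(X, y)
  fit <- fit_classifier(classifier_spec("DT"), tab$X, tab$y, seed = 83)
  imp <- permutation_importance(fit, tab, repeats = 5, seed = 83)
  expect_equal(imp$feature[imp$serial == 1L], "signal")
  expect_lt(abs(imp$score[imp$feature == "noise1"]), 0.05)
})

test_that("permutation importance variance shrinks with more repeats", {
  set.seed(89)
  n <- 300
  X <- cbind(signal = rnorm(n), noise = rnorm(n))
  y <- as.integer(X[, "signal"] + rnorm(n, 0, 0.5) > 0)
  tab <- labeled_table(X, y)
  fit <- fit_classifier(classifier_spec("DT"), tab$X, tab$y, seed = 89)
  score_at <- function(repeats, seeds) {
    vapply(seeds, function(s) {
      permutation_importance(fit, tab, repeats = repeats,
                             seed = s)$score[1]
    }, numeric(1))
  }
  few <- score_at(2L, 1:8)
  many <- score_at(16L, 1:8)
  expect_lt(stats::var(many), stats::var(few))
  expect_equal(mean(many), mean(few), tolerance = 0.1)
})
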