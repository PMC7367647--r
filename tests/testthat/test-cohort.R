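test_that("confusion rates report exact integer ratios", {
  co <- rbind(cohort_from_category_counts(22, 0, 0, 1, "cancer"),
              cohort_from_category_counts(0, 0, 1, 27, "control"))
  class(co) <- c("labeled_cohort", "data.frame")
  cr <- confusion_rates(co)
  expect_equal(cr$tp, 22); expect_equal(cr$fn, 1)
  expect_equal(cr$tn, 27); expect_equal(cr$fp, 1)
  expect_equal(cr$sensitivity, 22 / 23)
  expect_equal(round(cr$sensitivity_pct, 1), 95.7)
  expect_equal(cr$specificity, 27 / 28)
  expect_equal(round(cr$specificity_pct, 1), 96.4)

  perfect <- labeled_cohort(letters[1:4], rep(c("cancer", "control"), 2),
                            c(TRUE, FALSE, TRUE, FALSE))
  crp <- confusion_rates(perfect)
  expect_equal(crp$sensitivity, 1)
  expect_equal(crp$specificity, 1)

  only <- labeled_cohort(letters[1:3], rep("cancer", 3), c(TRUE, TRUE, FALSE))
  expect_error(confusion_rates(only), "both")
})

test_that("trapezoid AUC equals the pairwise-concordance oracle", {
  perfect <- labeled_cohort(letters[1:6], rep(c("cancer", "control"), each = 3),
                            positive = rep(c(TRUE, FALSE), each = 3),
                            statistic = c(9, 8, 7, 2, 1, 0))
  expect_equal(roc_auc(perfect)$auc, 1)

  set.seed(77)
  # large null cohort: statistic independent of label
  null <- labeled_cohort(sprintf("s%03d", 1:400),
                         rep(c("cancer", "control"), each = 200),
                         positive = rep(FALSE, 400),
                         statistic = rnorm(400))
  expect_lt(abs(roc_auc(null)$auc - 0.5), 0.08)

  # oracle identity on random cohorts, with and without ties
  for (r in 1:20) {
    n <- sample(8:30, 1)
    stat <- sample(0:6, n, replace = TRUE) + rnorm(n, sd = 0.2 * (r %% 2))
    lab <- sample(c("cancer", "control"), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    co <- labeled_cohort(sprintf("s%02d", 1:n), lab, stat > 3,
                         statistic = stat)
    expect_equal(roc_auc(co)$auc, oracle_auc(stat, lab == "cancer"),
                 tolerance = 1e-12)
  }

  const <- labeled_cohort(letters[1:4], rep(c("cancer", "control"), 2),
                          rep(TRUE, 4), statistic = rep(1, 4))
  expect_warning(rc <- roc_auc(const), "constant")
  expect_equal(rc$auc, 0.5)
})

test_that("the Youden-optimal cutoff prefers the smaller tied value", {
  sep <- labeled_cohort(letters[1:6], rep(c("cancer", "control"), each = 3),
                        positive = rep(c(TRUE, FALSE), each = 3),
                        statistic = c(9, 8, 5, 2, 1, 0))
  # any cutoff in (2, 5] separates; the smallest observed separating value is 5
  expect_equal(optimal_cutoff(roc_auc(sep)), 5)

  one <- labeled_cohort(letters[1:5], c("cancer", "cancer", "cancer",
                                        "control", "control"),
                        positive = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                        statistic = c(9, 7, 1, 3, 0))
  # J peaks uniquely at cutoff 7 (TPR 2/3, FPR 0)
  expect_equal(optimal_cutoff(roc_auc(one)), 7)
})

test_that("exact Fisher results reproduce the published size association", {
  fr <- fisher_exact_2x2(matrix(c(32, 6, 17, 18), 2, byrow = TRUE))
  expect_equal(fr$or_cmle, 5.50, tolerance = 0.005)
  expect_equal(fr$ci95[1], 1.70, tolerance = 0.005)
  expect_equal(fr$ci95[2], 20.3, tolerance = 0.005)
  expect_lt(fr$p_two_sided, 0.05)
  expect_equal(round(fr$p_two_sided, 3), 0.002)

  sym <- fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(sym$or_cmle, 1, tolerance = 1e-6)
  expect_equal(sym$p_two_sided, 1, tolerance = 1e-10)

  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
  expect_error(fisher_exact_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("two-sided Fisher p equals hypergeometric enumeration", {
  set.seed(31)
  for (r in 1:100) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p_two_sided, oracle_fisher_p(tab),
                 tolerance = 1e-10)
  }
})

test_that("covariate cross-tabs partition the cohort and test collapsed 2x2s", {
  co <- labeled_cohort(sprintf("s%d", 1:6), rep("cancer", 6),
                       positive = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
                       altered_count = c(4, 2, 0, 1, 0, 0))
  ct <- crosstab_by_group(co, c("a", "a", "a", "b", "b", "b"))
  expect_equal(sum(ct$rows$n), 6)
  expect_equal(ct$rows$ge3, c(1, 0))
  expect_equal(ct$rows$zero, c(1, 2))
  expect_equal(ct$rows$pct_positive, c(200 / 3, 100 / 3))

  # published tumor-size block: counts alone reproduce the printed rates
  size <- rbind(
    data.frame(level = ">=5", ge3 = 23, two = 3, one = 6, zero = 6),
    data.frame(level = "3-5", ge3 = 6, two = 1, one = 2, zero = 8),
    data.frame(level = "<3", ge3 = 1, two = 3, one = 4, zero = 10))
  blocks <- do.call(rbind, lapply(seq_len(nrow(size)), function(i) {
    b <- cohort_from_category_counts(size$ge3[i], size$two[i], size$one[i],
                                     size$zero[i], "cancer",
                                     prefix = size$level[i])
    b$cov <- size$level[i]
    b
  }))
  class(blocks) <- c("labeled_cohort", "data.frame")
  ct2 <- crosstab_by_group(blocks, blocks$cov, test_level = ">=5")
  expect_equal(round(ct2$rows$pct_positive, 1), c(84.2, 52.9, 44.4))
  expect_equal(unname(ct2$fisher$table[1, ]), c(32, 6))
  expect_equal(unname(ct2$fisher$table[2, ]), c(17, 18))
  expect_equal(ct2$fisher$or_cmle, 5.50, tolerance = 0.005)

  # missing covariates form their own row and never enter the test
  ctna <- crosstab_by_group(co, rep(NA_character_, 6))
  expect_equal(ctna$rows$level, "NA")
  expect_equal(ctna$rows$n, 6)
  expect_null(ctna$fisher)
  ctmix <- crosstab_by_group(co, c("a", "a", NA, "b", "b", NA),
                             test_level = "a")
  expect_equal(sum(ctmix$fisher$table), 4)
})

test_that("combined positivity is a logical OR with the expected gain", {
  expect_false(combine_tests(FALSE, FALSE))
  expect_true(combine_tests(TRUE, FALSE))
  expect_true(combine_tests(FALSE, TRUE))
  expect_true(combine_tests(TRUE, TRUE))

  set.seed(14)
  n <- 20000
  a <- runif(n) < 0.5
  b <- runif(n) < 0.4
  expect_equal(mean(combine_tests(a, b)), 1 - 0.5 * 0.6, tolerance = 0.02)
})
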