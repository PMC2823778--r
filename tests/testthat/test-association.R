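# The published stratified counts used throughout: female and male
# HLA-A*02-carrier strata of the pooled Italian MS case-control study.
female_counts <- rbind(case = c(HH = 26, RH = 146, RR = 165),
                       control = c(HH = 32, RH = 80, RR = 90))
male_counts <- rbind(case = c(HH = 18, RH = 85, RR = 75),
                     control = c(HH = 21, RH = 88, RR = 85))

test_that("the subject fixture reproduces the published stratum counts", {
  subj <- ms_study_subjects()
  gt_f <- tabulate_genotypes(subj, sex = "female", a02 = "yes")
  expect_equal(gt_f$counts, female_counts)
  expect_equal(gt_f$percentages["case", ], c(HH = 7.7, RH = 43.3, RR = 49.0))
  expect_equal(gt_f$percentages["control", ],
               c(HH = 15.8, RH = 39.6, RR = 44.6))
  gt_m <- tabulate_genotypes(subj, sex = "male", a02 = "yes")
  expect_equal(gt_m$counts, male_counts)
  expect_equal(gt_m$percentages["case", ], c(HH = 10.1, RH = 47.8, RR = 42.1))
  expect_equal(gt_m$percentages["control", ],
               c(HH = 10.8, RH = 45.4, RR = 43.8))
  # sex-by-status margins
  g <- gender_table(subj)
  expect_equal(g$counts, matrix(c(413L, 849L, 437L, 408L), 2,
                                dimnames = list(c("male", "female"),
                                                c("case", "control"))))
  expect_equal(g$percentages["female", ], c(case = 67.3, control = 48.3))
})

test_that("tabulation rejects empty strata", {
  subj <- ms_study_subjects()
  expect_error(tabulate_genotypes(subj[0, ]), "empty stratum")
  expect_error(tabulate_genotypes(subj, sex = "female", a02 = "no"),
               "empty stratum")
})

test_that("odds ratios and Woolf CIs match the published female stratum", {
  or1 <- odds_ratio(26, 165, 32, 90)
  expect_equal(round(or1$odds_ratio, 3), 0.443)
  expect_equal(round(or1$ci95, 3), c(0.249, 0.790))
  or2 <- odds_ratio(26, 146, 32, 80)
  expect_equal(round(or2$odds_ratio, 3), 0.445)
  expect_equal(round(or2$ci95, 3), c(0.248, 0.799))
  or3 <- odds_ratio(146, 165, 80, 90)
  expect_equal(round(or3$odds_ratio, 3), 0.995)
  expect_equal(round(or3$ci95, 3), c(0.684, 1.448))
})

test_that("odds ratio obeys label-swap reciprocity and symmetric tables give 1", {
  o1 <- odds_ratio(12, 31, 7, 45)$odds_ratio
  o2 <- odds_ratio(31, 12, 45, 7)$odds_ratio
  expect_equal(o1 * o2, 1, tolerance = 1e-12)
  os <- odds_ratio(10, 10, 10, 10)
  expect_equal(os$odds_ratio, 1)
  expect_equal(log(os$ci95[1]), -log(os$ci95[2]), tolerance = 1e-12)
})

test_that("a zero cell triggers the flagged Haldane correction", {
  o <- odds_ratio(0, 20, 5, 15)
  expect_true(o$haldane)
  expect_equal(o$odds_ratio, (0.5 * 15.5) / (20.5 * 5.5))
  expect_error(odds_ratio(-1, 2, 3, 4), "non-negative")
})

test_that("Pearson chi-squared reproduces the published p-values", {
  expect_equal(round(pearson_chi2(female_counts)$p, 3), 0.013)
  expect_equal(round(pearson_chi2(female_counts[, c("HH", "RR")])$p, 3), 0.005)
  expect_equal(round(pearson_chi2(female_counts[, c("HH", "RH")])$p, 3), 0.006)
  expect_equal(round(pearson_chi2(female_counts[, c("RH", "RR")])$p, 3), 0.981)
})

test_that("Pearson chi-squared is transpose-invariant and handles edge tables", {
  p1 <- pearson_chi2(female_counts)
  p2 <- pearson_chi2(t(female_counts))
  expect_equal(p1$chi2, p2$chi2, tolerance = 1e-12)
  # table exactly at independence
  expect_equal(pearson_chi2(rbind(c(10, 20), c(5, 10)))$chi2, 0)
  expect_equal(pearson_chi2(rbind(c(10, 20), c(5, 10)))$p, 1)
  expect_error(pearson_chi2(rbind(c(0, 0), c(5, 10))), "zero margin")
  # matches the base chisq.test statistic on an arbitrary table
  tab <- rbind(c(13, 7, 4), c(6, 12, 9))
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(pearson_chi2(tab)$chi2, unname(ref$statistic), tolerance = 1e-12)
})

test_that("Monte Carlo chi-squared converges to the asymptotic value", {
  mc <- monte_carlo_chi2(female_counts, n_reps = 100000, seed = 11)
  expect_lt(abs(mc$p_monte_carlo - 0.013), 3 * mc$mc_se)
  expect_equal(mc$n_reps, 100000L)
  expect_equal(mc$seed, 11L)
})

test_that("Monte Carlo chi-squared matches full fixed-margin enumeration", {
  tab <- rbind(c(5, 2), c(1, 7))
  exact <- enum_chi2_p_2x2(tab)
  mc <- monte_carlo_chi2(tab, n_reps = 50000, seed = 4)
  se <- sqrt(exact * (1 - exact) / 50000)
  expect_lt(abs(mc$p_monte_carlo - exact), 3 * se + 1e-3)
})

test_that("degenerate single-column table gives Monte Carlo p = 1", {
  expect_equal(monte_carlo_chi2(matrix(c(4, 9), 2, 1), n_reps = 1000)$p_monte_carlo, 1)
  expect_error(monte_carlo_chi2(female_counts, n_reps = 10), "at least 1000")
})

test_that("Hardy-Weinberg test matches the closed-form oracle", {
  res <- hwe_test(32, 80, 90)
  # oracle computed by hand: p_H = 144/404, expected (25.66, 92.66, 83.67)
  p <- (2 * 32 + 80) / (2 * 202)
  e <- 202 * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  expect_equal(res$allele_freq, p)
  expect_equal(unname(res$expected), e)
  expect_equal(res$chi2, sum((c(32, 80, 90) - e)^2 / e), tolerance = 1e-12)
  expect_equal(round(res$chi2, 2), 3.78)
  expect_gt(res$p, 0.05)
  expect_lt(res$p, 0.06)
})

test_that("Hardy-Weinberg boundary cases", {
  perfect <- hwe_test(25, 50, 25)
  expect_equal(perfect$chi2, 0)
  expect_equal(perfect$p, 1)
  extreme <- hwe_test(50, 0, 50)
  expect_equal(extreme$chi2, 100)
  expect_lt(extreme$p, 1e-20)
  expect_error(hwe_test(0, 0, 0), "total > 0")
})

test_that("cohort homogeneity licenses pooling for same-source cohorts", {
  identical_p <- cohort_homogeneity(c(HH = 20, RH = 50, RR = 60),
                                    c(HH = 20, RH = 50, RR = 60),
                                    n_reps = 2000, seed = 1)
  expect_equal(identical_p$chi2, 0)
  expect_equal(identical_p$p_asymptotic, 1)
  # clearly different allele frequencies are detected
  set.seed(31)
  h1 <- table(factor(sample(c("HH", "RH", "RR"), 500, TRUE,
                            prob = c(0.04, 0.32, 0.64)), c("HH", "RH", "RR")))
  h2 <- table(factor(sample(c("HH", "RH", "RR"), 500, TRUE,
                            prob = c(0.25, 0.5, 0.25)), c("HH", "RH", "RR")))
  diff_p <- cohort_homogeneity(c(h1), c(h2), n_reps = 2000, seed = 2)
  expect_lt(diff_p$p_asymptotic, 0.001)
})

test_that("onset-age comparison detects shifts and reports group summaries", {
  expect_error(onset_age_compare(c(30, 31), c("a", "b")), "n >= 2")
  set.seed(8)
  ages <- c(rnorm(30, 30, 5), rnorm(30, 40, 5))
  g <- rep(c("RR", "HH"), each = 30)
  res <- onset_age_compare(ages, g, n_perm = 2000, seed = 3)
  expect_lt(res$p, 0.01)
  expect_equal(res$summary$n, c(30L, 30L))
  expect_equal(res$summary$mean,
               round(as.numeric(tapply(ages, g, mean)[c("HH", "RR")]), 2))
  # identical groups: F = 0, p = 1
  same <- onset_age_compare(rep(c(28, 32, 36), 2),
                            rep(c("a", "b"), each = 3))
  expect_equal(same$statistic_value, 0)
  expect_equal(same$p, 1)
})
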