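test_that("SP is 1000 times fragment over consumed substrate", {
  expect_equal(compute_sp(50, 200), 250)
  expect_equal(compute_sp(0, 200), 0)
  expect_error(compute_sp(50, 0), "undefined")
  expect_error(compute_sp(50, -3), "undefined")
})

test_that("consumption bins partition [0, 1] with half-open boundaries", {
  expect_equal(as.character(assign_bin(0.10)), "lt25")
  expect_equal(as.character(assign_bin(0.25)), "b25_35")
  expect_equal(as.character(assign_bin(0.35)), "b35_50")
  expect_equal(as.character(assign_bin(0.50)), "excluded")
  expect_equal(as.character(assign_bin(1)), "excluded")
  expect_error(assign_bin(1.2), "\\[0, 1\\]")
  # every consumption maps to exactly one bin
  x <- seq(0, 1, by = 0.001)
  expect_false(anyNA(assign_bin(x)))
})

test_that("within-set standardization is the sample-SD z-score", {
  est <- data.frame(set_id = "s1", fragment = "frag_10_18",
                    sp = c(100, 200, 300))
  z <- standardize_within_set(est)$sp_standardized
  # sample (n-1) SD of {100, 200, 300} is 100, so the z-scores are -1, 0, 1
  expect_equal(z, (est$sp - 200) / sd(est$sp))
  expect_equal(z, c(-1, 0, 1))
  # a group comparison is invariant (up to the affine map) within one set
  est$genotype <- c("RR", "RR", "HH")
  raw_order <- order(est$sp)
  std_order <- order(z)
  expect_equal(raw_order, std_order)
})

test_that("zero-variance sets are flagged and passed through", {
  est <- data.frame(set_id = "s1", fragment = "f", sp = c(5, 5, 5))
  expect_warning(out <- standardize_within_set(est), "unstandardized")
  expect_equal(out$sp_standardized, est$sp)
  expect_false(any(out$standardized))
})

test_that("the per-set batch factor cancels out of SP", {
  cfg <- digestion_sim_config(batch_scale_sd = 0.8, noise_sd = 0, seed = 21)
  dig <- simulate_digestion(cfg)
  # batch factors really do differ across sets in the raw signals
  s0_by_set <- tapply(dig$substrate_signal[dig$time_min == 0],
                      dig$set_id[dig$time_min == 0], identity)
  expect_gt(diff(range(unlist(s0_by_set))), 1)
  est <- sp_estimates(dig)
  # ... yet SP (same detector channel in numerator and denominator) is
  # identical across sets that share a yield, so cross-set comparisons do
  # not see the batch factor
  epi <- est[est$fragment == "frag_10_18" & est$pa28 == "absent", ]
  expect_lt(diff(range(epi$sp)), 1e-9)
  # zero within-set variance is flagged rather than divided by zero
  expect_warning(standardize_within_set(epi), "unstandardized")
})

test_that("standardized SP aligns sets that differ by scale under noise", {
  cfg <- digestion_sim_config(batch_scale_sd = 0.8, noise_sd = 0.1, seed = 22)
  est <- standardize_within_set(sp_estimates(simulate_digestion(cfg)))
  expect_true(all(est$standardized))
  z <- est$sp_standardized
  key <- interaction(est$set_id, est$fragment)
  expect_true(all(abs(tapply(z, key, mean)) < 1e-9))
  expect_true(all(abs(tapply(z, key, sd) - 1) < 1e-9))
})

test_that("noiseless SP equals 1000 times the configured yield", {
  cfg <- noiseless_config(seed = 2)
  est <- sp_estimates(simulate_digestion(cfg))
  rr_core <- est$fragment == "frag_10_18" & est$genotype == "RR"
  expect_equal(unique(round(est$sp[rr_core], 9)),
               1000 * cfg$epitope_yield_base)
  hh_pa28 <- est$fragment == "frag_10_18" & est$genotype == "HH" &
    est$pa28 == "present"
  expect_equal(unique(round(est$sp[hh_pa28], 9)),
               1000 * cfg$epitope_yield_base * cfg$h_carrier_yield_ratio)
})

test_that("noiseless percent decrease equals 100*(1 - yield ratio) in every bin", {
  cfg <- noiseless_config(h_carrier_yield_ratio = 0.712, seed = 3)
  est <- sp_estimates(simulate_digestion(cfg))
  for (b in c("lt25", "b25_35", "b35_50")) {
    cmp <- compare_sp_by_genotype(est, bin = b, pa28 = "present")
    expect_equal(cmp$percent_decrease, 28.8, tolerance = 1e-9)
    expect_lt(cmp$p, 0.001)
  }
  # no effect injected without PA28
  cmp0 <- compare_sp_by_genotype(est, bin = "b25_35", pa28 = "absent")
  expect_equal(cmp0$percent_decrease, 0, tolerance = 1e-9)
})

test_that("no genotype effect when the yield ratio is 1", {
  cfg <- noiseless_config(h_carrier_yield_ratio = 1, seed = 4)
  est <- sp_estimates(simulate_digestion(cfg))
  cmp <- compare_sp_by_genotype(est, bin = "lt25", pa28 = "present")
  expect_equal(cmp$percent_decrease, 0, tolerance = 1e-9)
})

test_that("three-group permutation ANOVA mode returns an F and percent decrease", {
  cfg <- digestion_sim_config(seed = 8)
  est <- sp_estimates(simulate_digestion(cfg))
  cmp <- compare_sp_by_genotype(est, bin = "lt25", pa28 = "present",
                                mode = "three_group_mc_anova", seed = 1)
  expect_equal(cmp$statistic_name, "F")
  expect_true(cmp$p >= 0 && cmp$p <= 1)
  expect_true(is.finite(cmp$percent_decrease))
})

test_that("exact Mann-Whitney matches enumeration and wilcox.test", {
  # complete separation at n = 6 + 6: U = 0, p = 2/924
  res <- compare_sp_pa28(7:12, 1:6)
  expect_equal(res$statistic_value, 36)  # U of the larger group
  expect_equal(res$p, 2 / choose(12, 6), tolerance = 1e-12)
  expect_equal(format(round(res$p, 3), nsmall = 3), "0.002")
  # complete separation at n = 3 + 3
  expect_equal(mann_whitney(1:3, 4:6)$p, 0.1, tolerance = 1e-12)
  # random continuous inputs agree with the exact wilcox.test oracle
  set.seed(99)
  for (i in 1:10) {
    n1 <- sample(3:6, 1)
    n2 <- sample(3:6, 1)
    x <- rnorm(n1)
    y <- rnorm(n2)
    ours <- mann_whitney(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$u, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("balanced identical samples give Mann-Whitney p = 1", {
  x <- c(1, 2, 3, 4)
  expect_equal(mann_whitney(x, x)$p, 1)
})

test_that("Mann-Whitney handles ties by permuting observed values", {
  x <- c(1, 1, 2, 3)
  y <- c(1, 2, 2, 4)
  ours <- mann_whitney(x, y)
  expect_true(ours$p > 0 && ours$p <= 1)
  # large-sample path applies a tie-corrected normal approximation
  set.seed(3)
  xl <- sample(1:4, 20, replace = TRUE)
  yl <- sample(1:4, 20, replace = TRUE)
  ours_l <- mann_whitney(xl, yl)
  ref <- suppressWarnings(wilcox.test(xl, yl, exact = FALSE, correct = FALSE))
  expect_equal(ours_l$p, ref$p.value, tolerance = 1e-9)
})

test_that("Levene test matches car::leveneTest with mean centering", {
  skip_if_not_installed("car")
  set.seed(123)
  x <- c(rnorm(12, sd = 1), rnorm(15, sd = 3))
  g <- rep(c("a", "b"), c(12, 15))
  ours <- levene_test(x, g)
  ref <- car::leveneTest(x, factor(g), center = mean)
  expect_equal(ours$statistic_value, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(ours$p, ref[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("Levene degenerate and power cases behave as expected", {
  expect_equal(levene_test(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))$statistic_value, 0)
  expect_equal(levene_test(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))$p, 1)
  set.seed(5)
  x <- c(rep(1, 20), rnorm(20, sd = 5))
  g <- rep(c("a", "b"), each = 20)
  expect_lt(levene_test(x, g)$p, 0.01)
})
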