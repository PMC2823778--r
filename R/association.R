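#' Tabulate genotype counts in a case-control stratum
#'
#' Counts LMP2 genotypes by disease status within an optional sex and
#' HLA-A*02-carriage stratum. Subjects with unknown carriage or missing
#' genotype are excluded. Percentages are computed within status rows and
#' rounded to 1 decimal.
#'
#' @param subjects subject data.frame (see [read_subjects()] for the schema).
#' @param sex optional filter, `"female"` or `"male"`.
#' @param a02 optional filter on HLA-A*02 carriage, `"yes"` or `"no"`.
#' @param cohorts optional character vector of case cohort labels to keep
#'   (controls are always kept).
#' @return an object of class `genotype_table`: `counts` (2 x 3 matrix,
#'   rows case/control, columns HH/RH/RR), `percentages`, `stratum`.
#' @export
tabulate_genotypes <- function(subjects, sex = NULL, a02 = NULL,
                               cohorts = NULL) {
  d <- subjects
  if (!is.null(sex)) d <- d[d$sex %in% sex, , drop = FALSE]
  if (!is.null(a02)) {
    d <- d[!is.na(d$a02_carrier) & d$a02_carrier %in% a02, , drop = FALSE]
  }
  if (!is.null(cohorts)) {
    d <- d[d$status == "control" | d$cohort %in% cohorts, , drop = FALSE]
  }
  d <- d[!is.na(d$lmp2) & d$lmp2 %in% c("HH", "RH", "RR"), , drop = FALSE]
  counts <- matrix(0L, nrow = 2, ncol = 3,
                   dimnames = list(c("case", "control"), c("HH", "RH", "RR")))
  tab <- table(factor(d$status, c("case", "control")),
               factor(d$lmp2, c("HH", "RH", "RR")))
  counts[] <- as.integer(tab)
  if (any(rowSums(counts) == 0)) {
    stop("empty stratum: no genotyped cases or controls after filtering",
         call. = FALSE)
  }
  pct <- round(100 * counts / rowSums(counts), 1)
  structure(list(counts = counts, percentages = pct,
                 stratum = list(sex = sex, a02 = a02, cohorts = cohorts)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("Genotype counts (percentages)\n")
  disp <- matrix(sprintf("%d (%.1f)", x$counts, x$percentages),
                 nrow = 2, dimnames = dimnames(x$counts))
  print(disp, quote = FALSE)
  invisible(x)
}

#' Sex-by-status table
#'
#' Counts of male/female subjects among cases and controls with column
#' percentages rounded to 1 decimal.
#'
#' @param subjects subject data.frame.
#' @return list with `counts` (2 x 2, rows male/female, columns case/control)
#'   and `percentages`.
#' @export
gender_table <- function(subjects) {
  tab <- table(factor(subjects$sex, c("male", "female")),
               factor(subjects$status, c("case", "control")))
  counts <- matrix(as.integer(tab), nrow = 2,
                   dimnames = list(c("male", "female"), c("case", "control")))
  pct <- round(100 * sweep(counts, 2, colSums(counts), "/"), 1)
  list(counts = counts, percentages = pct)
}

#' Odds ratio with Woolf confidence interval
#'
#' For a 2 x 2 extraction (case-genotype1, case-genotype2, control-genotype1,
#' control-genotype2) computes `OR = (a * d) / (b * c)` — the odds of
#' genotype1 in cases relative to controls — with the Woolf (log-scale) 95%
#' interval `exp(log OR +/- 1.959964 * sqrt(1/a + 1/b + 1/c + 1/d))`. When
#' any cell is zero, the Haldane correction (+0.5 to every cell) is applied
#' and flagged.
#'
#' @param a,b cases with genotype 1 and genotype 2.
#' @param c,d controls with genotype 1 and genotype 2.
#' @return an object of class `or_estimate`: `odds_ratio`, `ci95`,
#'   `log_se`, `haldane` flag.
#' @examples
#' odds_ratio(26, 165, 32, 90)  # OR 0.443, CI 0.249-0.790
#' @export
odds_ratio <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  haldane <- any(cells == 0)
  if (haldane) cells <- cells + 0.5
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * 1.959964 * se)
  structure(list(odds_ratio = unname(or), ci95 = unname(ci),
                 log_se = unname(se), haldane = haldane),
            class = "or_estimate")
}

#' @export
print.or_estimate <- function(x, ...) {
  cat(sprintf("OR = %.3f (95%% CI %.3f-%.3f)%s\n", x$odds_ratio,
              x$ci95[1], x$ci95[2],
              if (x$haldane) " [Haldane +0.5 applied]" else ""))
  invisible(x)
}

#' Pearson chi-squared test of a contingency table
#'
#' Classical Pearson statistic without continuity correction,
#' `df = (r - 1)(c - 1)`. A table with a single row or column has no degrees
#' of freedom and returns chi2 = 0, p = 1.
#'
#' @param tab matrix of non-negative counts with no zero margin.
#' @return list with `chi2`, `df`, `p`.
#' @export
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(!is.finite(tab))) {
    stop("counts must be non-negative and finite", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("table has a zero margin", call. = FALSE)
  }
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  if (df == 0) {
    return(list(chi2 = 0, df = 0L, p = 1))
  }
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - e)^2 / e)
  list(chi2 = chi2, df = as.integer(df),
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Monte Carlo Pearson chi-squared p-value
#'
#' Samples `n_reps` tables from the fixed-margins null via Patefield's
#' algorithm ([stats::r2dtable()]; every sampled table has exactly the
#' observed margins) and estimates
#' `p = (1 + #\{chi2_sim >= chi2_obs\}) / (n_reps + 1)` (add-one estimator,
#' so p > 0). The Monte Carlo standard error `sqrt(p (1 - p) / n_reps)` is
#' reported.
#'
#' @param tab matrix of non-negative integer counts with no zero margin.
#' @param n_reps number of simulated tables (>= 1000).
#' @param seed seed recorded in the output.
#' @return list with `p_monte_carlo`, `mc_se`, `chi2`, `df`, `p_asymptotic`,
#'   `n_reps`, `seed`.
#' @export
monte_carlo_chi2 <- function(tab, n_reps = 10000, seed = NULL) {
  if (n_reps < 1000) {
    stop("'n_reps' must be at least 1000", call. = FALSE)
  }
  tab <- as.matrix(tab)
  obs <- pearson_chi2(tab)
  if (obs$df == 0) {
    return(list(p_monte_carlo = 1, mc_se = 0, chi2 = 0, df = 0L,
                p_asymptotic = 1, n_reps = as.integer(n_reps),
                seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
  }
  if (!is.null(seed)) set.seed(seed)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  e <- outer(rs, cs) / sum(tab)
  sims <- stats::r2dtable(n_reps, rs, cs)
  chi_sim <- vapply(sims, function(s) sum((s - e)^2 / e), numeric(1))
  hits <- sum(stat_ge(chi_sim, obs$chi2))
  p <- (1 + hits) / (n_reps + 1)
  list(p_monte_carlo = p, mc_se = sqrt(p * (1 - p) / n_reps),
       chi2 = obs$chi2, df = obs$df, p_asymptotic = obs$p,
       n_reps = as.integer(n_reps),
       seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Pairwise genotype contrast within a stratum table
#'
#' Extracts the 2 x 2 subtable for two genotypes from a [tabulate_genotypes()]
#' result and reports the odds ratio with Woolf CI, the asymptotic Pearson
#' chi-squared p and the Monte Carlo p.
#'
#' @param gt a `genotype_table`.
#' @param g1,g2 genotype column names, e.g. `"HH"`, `"RR"`; the odds ratio is
#'   for `g1` relative to `g2`.
#' @param n_reps,seed Monte Carlo settings (see [monte_carlo_chi2()]).
#' @return an object of class `association_result`.
#' @examples
#' \dontrun{
#' gt <- tabulate_genotypes(ms_study_subjects(), sex = "female", a02 = "yes")
#' genotype_contrast(gt, "HH", "RR", seed = 1)
#' }
#' @export
genotype_contrast <- function(gt, g1, g2, n_reps = 10000, seed = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  sub <- gt$counts[, c(g1, g2), drop = FALSE]
  or <- odds_ratio(sub["case", g1], sub["case", g2],
                   sub["control", g1], sub["control", g2])
  mc <- monte_carlo_chi2(sub, n_reps = n_reps, seed = seed)
  structure(list(comparison = sprintf("%s vs %s", g1, g2),
                 odds_ratio = or$odds_ratio, ci95 = or$ci95,
                 haldane = or$haldane,
                 chi2 = mc$chi2, df = mc$df,
                 p_asymptotic = mc$p_asymptotic,
                 p_monte_carlo = mc$p_monte_carlo, mc_se = mc$mc_se,
                 n_reps = mc$n_reps, seed = mc$seed,
                 counts = sub),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s: OR = %.3f (95%% CI %.3f-%.3f), chi2 = %.3f (df %d), p = %.3f [MC p = %.4f, %d reps]\n",
              x$comparison, x$odds_ratio, x$ci95[1], x$ci95[2],
              x$chi2, x$df, x$p_asymptotic, x$p_monte_carlo, x$n_reps))
  invisible(x)
}

#' Hardy-Weinberg equilibrium test
#'
#' Pearson chi-squared test (df = 1, no continuity correction) of observed
#' genotype counts against the proportions p^2, 2pq, q^2 expected from the
#' observed allele frequency.
#'
#' @param n_hh,n_rh,n_rr observed genotype counts.
#' @return an object of class `hwe_result`: `observed`, `expected`,
#'   `allele_freq` (frequency of H), `chi2`, `df`, `p`.
#' @examples
#' hwe_test(32, 80, 90)  # p ~ 0.052
#' @export
hwe_test <- function(n_hh, n_rh, n_rr) {
  obs <- c(HH = n_hh, RH = n_rh, RR = n_rr)
  if (any(obs < 0) || any(obs != floor(obs)) || sum(obs) == 0) {
    stop("genotype counts must be non-negative integers with total > 0",
         call. = FALSE)
  }
  n <- sum(obs)
  p <- (2 * n_hh + n_rh) / (2 * n)
  e <- n * c(HH = p^2, RH = 2 * p * (1 - p), RR = (1 - p)^2)
  if (p == 0 || p == 1) {
    # monomorphic: expected equals observed by construction
    chi2 <- 0
  } else {
    chi2 <- sum((obs - e)^2 / e)
  }
  structure(list(observed = obs, expected = e, allele_freq = p,
                 chi2 = chi2, df = 1L,
                 p = stats::pchisq(chi2, 1, lower.tail = FALSE)),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("Hardy-Weinberg test: H allele freq = %.4f, chi2 = %.4f (df 1), p = %.4g\n",
              x$allele_freq, x$chi2, x$p))
  invisible(x)
}

#' Homogeneity of genotype distributions between two case cohorts
#'
#' Pearson and Monte Carlo chi-squared comparison of the genotype counts of
#' two cohorts; a non-significant result licenses pooling them.
#'
#' @param counts1,counts2 named genotype count vectors (same genotype names).
#' @param n_reps,seed Monte Carlo settings.
#' @return list with the stacked `table`, `chi2`, `df`, `p_asymptotic`,
#'   `p_monte_carlo`, `mc_se`, `n_reps`, `seed`.
#' @export
cohort_homogeneity <- function(counts1, counts2, n_reps = 10000, seed = NULL) {
  if (is.null(names(counts1)) || !identical(names(counts1), names(counts2))) {
    stop("cohort count vectors must share identical genotype names",
         call. = FALSE)
  }
  tab <- rbind(cohort1 = counts1, cohort2 = counts2)
  mc <- monte_carlo_chi2(tab, n_reps = n_reps, seed = seed)
  list(table = tab, chi2 = mc$chi2, df = mc$df,
       p_asymptotic = mc$p_asymptotic, p_monte_carlo = mc$p_monte_carlo,
       mc_se = mc$mc_se, n_reps = mc$n_reps, seed = mc$seed)
}

#' Compare onset ages across groups by permutation ANOVA
#'
#' Permutation one-way F test of onset age across genotype or carrier groups,
#' with group means and standard deviations reported to 2 decimals.
#'
#' @param ages onset ages in years.
#' @param groups group labels; >= 2 groups with n >= 2 each.
#' @param n_perm,seed permutation settings.
#' @return a `perm_anova` result with a `summary` data.frame attached
#'   (`group`, `n`, `mean`, `sd`).
#' @export
onset_age_compare <- function(ages, groups, n_perm = 10000, seed = NULL) {
  keep <- !is.na(ages) & !is.na(groups)
  ages <- ages[keep]
  groups <- droplevels(as.factor(groups[keep]))
  tab <- table(groups)
  if (nlevels(groups) < 2 || any(tab < 2)) {
    stop("need >= 2 groups with n >= 2 onset ages each", call. = FALSE)
  }
  res <- perm_anova(ages, groups, n_perm = n_perm, seed = seed)
  res$summary <- data.frame(group = levels(groups), n = as.integer(tab),
                            mean = round(as.numeric(tapply(ages, groups, mean)), 2),
                            sd = round(as.numeric(tapply(ages, groups, stats::sd)), 2),
                            stringsAsFactors = FALSE)
  res
}
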