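#' Run the full case-control association pipeline
#'
#' Reproduces the study's association surface from a subject table: the
#' sex-by-status table, per-stratum (sex x HLA-A*02 carriage) genotype tables
#' with the overall 2 x 3 chi-squared (asymptotic and Monte Carlo) and the
#' three pairwise genotype contrasts (odds ratio with Woolf CI, asymptotic and
#' Monte Carlo p), Hardy-Weinberg tests of cases and controls, linkage
#' disequilibrium of LMP2 60H with the two carrier loci in female controls,
#' cohort homogeneity when two case cohorts are present, and onset-age
#' comparisons. Every stochastic block records its `n_reps`/`n_perm` and
#' seed; runs with identical input and seed produce identical output.
#'
#' @param subjects subject data.frame or path to a subject CSV/TSV.
#' @param n_reps Monte Carlo replicates for chi-squared p-values.
#' @param n_perm permutations for onset-age tests.
#' @param seed master seed; panel seeds are derived from it.
#' @param output_dir optional directory; if given, writes
#'   `association_report.json` and per-stratum TSV tables there.
#' @return a list of class `association_report`.
#' @export
run_association <- function(subjects, n_reps = 10000, n_perm = 10000,
                            seed = 1L, output_dir = NULL) {
  if (is.character(subjects)) subjects <- read_subjects(subjects)
  report <- list(schema_version = "1.0",
                 n_reps = as.integer(n_reps), seed = as.integer(seed))
  report$gender <- gender_table(subjects)

  strata <- list(female_a02pos = list(sex = "female", a02 = "yes"),
                 male_a02pos = list(sex = "male", a02 = "yes"))
  k <- 0L
  report$strata <- lapply(strata, function(s) {
    gt <- tryCatch(tabulate_genotypes(subjects, sex = s$sex, a02 = s$a02),
                   error = function(e) NULL)
    if (is.null(gt)) return(list(note = "empty stratum"))
    k <<- k + 1L
    overall <- monte_carlo_chi2(gt$counts, n_reps = n_reps,
                                seed = substream_seed(seed, k))
    contrasts <- lapply(list(c("HH", "RR"), c("HH", "RH"), c("RH", "RR")),
                        function(pair) {
                          k <<- k + 1L
                          genotype_contrast(gt, pair[1], pair[2],
                                            n_reps = n_reps,
                                            seed = substream_seed(seed, k))
                        })
    names(contrasts) <- vapply(contrasts, `[[`, "", "comparison")
    list(stratum = s, counts = gt$counts, percentages = gt$percentages,
         overall = overall, contrasts = contrasts)
  })

  genotyped <- subjects[!is.na(subjects$lmp2), , drop = FALSE]
  report$hwe <- lapply(c(case = "case", control = "control"), function(st) {
    g <- table(factor(genotyped$lmp2[genotyped$status == st],
                      c("HH", "RH", "RR")))
    if (sum(g) == 0) return(list(note = "no genotyped subjects"))
    unclass(hwe_test(g["HH"], g["RH"], g["RR"]))
  })

  fc <- subjects[subjects$status == "control" & subjects$sex == "female" &
                   !is.na(subjects$lmp2), , drop = FALSE]
  report$ld_female_controls <- lapply(
    c(a02 = "a02_carrier", drb115 = "drb115_carrier"),
    function(col) {
      tryCatch(unclass(em_haplotype_freqs(lmp2_to_count(fc$lmp2),
                                          carrier_to_count(fc[[col]]))),
               error = function(e) list(note = conditionMessage(e)))
    })

  cohorts <- setdiff(unique(subjects$cohort[subjects$status == "case"]),
                     c(NA, "pooled"))
  if (length(cohorts) >= 2) {
    g1 <- table(factor(subjects$lmp2[subjects$status == "case" &
                                       subjects$cohort == cohorts[1]],
                       c("HH", "RH", "RR")))
    g2 <- table(factor(subjects$lmp2[subjects$status == "case" &
                                       subjects$cohort == cohorts[2]],
                       c("HH", "RH", "RR")))
    report$cohort_homogeneity <- tryCatch(
      cohort_homogeneity(c(g1), c(g2), n_reps = n_reps,
                         seed = substream_seed(seed, 100L)),
      error = function(e) list(note = conditionMessage(e)))
  }

  cases <- subjects[subjects$status == "case", , drop = FALSE]
  fa <- cases[cases$sex == "female" & !is.na(cases$a02_carrier) &
                cases$a02_carrier == "yes" & !is.na(cases$lmp2), , drop = FALSE]
  report$onset_by_genotype <- tryCatch(
    unclass(onset_age_compare(fa$onset_age, fa$lmp2, n_perm = n_perm,
                              seed = substream_seed(seed, 101L))),
    error = function(e) list(note = conditionMessage(e)))
  ac <- cases[cases$a02_carrier %in% c("yes", "no"), , drop = FALSE]
  report$onset_by_a02 <- tryCatch(
    unclass(onset_age_compare(ac$onset_age, ac$a02_carrier, n_perm = n_perm,
                              seed = substream_seed(seed, 102L))),
    error = function(e) list(note = conditionMessage(e)))

  class(report) <- "association_report"
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_json_report(report_to_plain(report),
                      file.path(output_dir, "association_report.json"))
    for (nm in names(report$strata)) {
      st <- report$strata[[nm]]
      if (!is.null(st$counts)) {
        write_tsv(as.data.frame(st$counts),
                  file.path(output_dir, paste0("genotypes_", nm, ".tsv")))
      }
    }
  }
  report
}

#' Run the full digestion / Specific Production pipeline
#'
#' From a digestion table: fits first-order kinetics per degradation set,
#' compares K1 across genotypes within each PA28 condition (permutation
#' ANOVA), computes SP estimates, standardizes them within sets, and for each
#' consumption bin and PA28 condition tests the genotype effect on the epitope
#' SP (H-carrier t with Levene check, three-group permutation F, percent
#' decrease) and the PA28 effect (Mann-Whitney on SP with vs without PA28,
#' per bin). Deterministic given the seed.
#'
#' @param digestion digestion data.frame or path to a digestion CSV/TSV.
#' @param n_perm permutations for the ANOVA tests.
#' @param seed master seed.
#' @param use_standardized run group tests on within-set standardized SP
#'   (percent decreases always come from raw SP).
#' @param output_dir optional directory for `digestion_report.json` and TSV
#'   tables.
#' @return a list of class `digestion_report`.
#' @export
run_digestion <- function(digestion, n_perm = 10000, seed = 1L,
                          use_standardized = FALSE, output_dir = NULL) {
  if (is.character(digestion)) digestion <- read_digestion(digestion)
  check_digestion(digestion)
  report <- list(schema_version = "1.0", n_perm = as.integer(n_perm),
                 seed = as.integer(seed),
                 use_standardized = use_standardized)

  fits <- fit_kinetics(digestion)
  report$kinetics <- fits
  report$k1_by_genotype <- lapply(
    c(present = "present", absent = "absent"),
    function(cond) {
      f <- fits[fits$pa28 == cond, , drop = FALSE]
      tryCatch(unclass(compare_k1(f$k1, f$genotype, n_perm = n_perm,
                                  seed = substream_seed(seed, 1L))),
               error = function(e) list(note = conditionMessage(e)))
    })

  est <- standardize_within_set(sp_estimates(digestion))
  report$sp_summary <- stats::aggregate(
    sp ~ genotype + pa28 + bin + fragment, data = est, FUN = mean)

  bins <- c("lt25", "b25_35", "b35_50")
  k <- 1L
  report$genotype_effect <- lapply(
    c(present = "present", absent = "absent"),
    function(cond) {
      out <- lapply(stats::setNames(bins, bins), function(b) {
        k <<- k + 1L
        tt <- tryCatch(
          unclass(compare_sp_by_genotype(est, bin = b, pa28 = cond,
                                         mode = "h_carrier_t",
                                         use_standardized = use_standardized)),
          error = function(e) list(note = conditionMessage(e)))
        k <<- k + 1L
        av <- tryCatch(
          unclass(compare_sp_by_genotype(est, bin = b, pa28 = cond,
                                         mode = "three_group_mc_anova",
                                         use_standardized = use_standardized,
                                         n_perm = n_perm,
                                         seed = substream_seed(seed, k))),
          error = function(e) list(note = conditionMessage(e)))
        list(h_carrier_t = tt, three_group_anova = av)
      })
      out
    })

  report$pa28_effect <- lapply(stats::setNames(bins, bins), function(b) {
    epi <- est[est$fragment == "frag_10_18" & est$bin == b, , drop = FALSE]
    x <- epi$sp[epi$pa28 == "present"]
    y <- epi$sp[epi$pa28 == "absent"]
    if (length(x) < 1 || length(y) < 1) {
      return(list(note = "a condition has no estimates in this bin"))
    }
    unclass(compare_sp_pa28(x, y))
  })

  class(report) <- "digestion_report"
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_json_report(report_to_plain(report),
                      file.path(output_dir, "digestion_report.json"))
    write_tsv(fits, file.path(output_dir, "kinetics_fits.tsv"))
    write_tsv(report$sp_summary, file.path(output_dir, "sp_summary.tsv"))
  }
  report
}

# strip classes/attributes so jsonlite serializes plainly and reproducibly
report_to_plain <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    return(lapply(unclass(x), report_to_plain))
  }
  if (is.matrix(x)) {
    return(as.data.frame(x))
  }
  x
}
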