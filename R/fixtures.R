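#' Subject-level reconstruction of the published study tables
#'
#' Rebuilds a subject table from the published summary counts of the Italian
#' multiple-sclerosis case-control study: the sex-by-status margins (1262 MS
#' cases: 413 male / 849 female; 845 controls: 437 male / 408 female) and the
#' LMP2 codon-60 genotype counts of the two HLA-A*02-carrier strata
#' (females: cases 26 HH / 146 RH / 165 RR vs controls 32 / 80 / 90; males:
#' cases 18 / 85 / 75 vs controls 21 / 88 / 85). Subjects outside those
#' genotyped strata are filled in with `lmp2 = NA` and
#' `a02_carrier = "unknown"` so that only published cells enter any analysis.
#' Onset ages and HLA-DRB1*15 carriage were published as summaries only and
#' are left `NA`/`"unknown"`. This is a synthetic expansion of printed
#' marginal tables, not deposited subject data.
#'
#' @return a subject data.frame in the standard schema (see
#'   [read_subjects()]).
#' @examples
#' subj <- ms_study_subjects()
#' tabulate_genotypes(subj, sex = "female", a02 = "yes")
#' @export
ms_study_subjects <- function() {
  strata <- list(
    list(sex = "female", a02 = "yes", status = "case",
         lmp2 = c(HH = 26, RH = 146, RR = 165)),
    list(sex = "female", a02 = "yes", status = "control",
         lmp2 = c(HH = 32, RH = 80, RR = 90)),
    list(sex = "male", a02 = "yes", status = "case",
         lmp2 = c(HH = 18, RH = 85, RR = 75)),
    list(sex = "male", a02 = "yes", status = "control",
         lmp2 = c(HH = 21, RH = 88, RR = 85))
  )
  blocks <- lapply(strata, function(s) {
    data.frame(status = s$status, sex = s$sex,
               lmp2 = rep(names(s$lmp2), s$lmp2),
               a02_carrier = s$a02, stringsAsFactors = FALSE)
  })
  genotyped <- do.call(rbind, blocks)

  totals <- list(case = c(male = 413, female = 849),
                 control = c(male = 437, female = 408))
  filler <- do.call(rbind, lapply(names(totals), function(st) {
    do.call(rbind, lapply(names(totals[[st]]), function(sx) {
      have <- sum(genotyped$status == st & genotyped$sex == sx)
      need <- totals[[st]][sx] - have
      if (need <= 0) return(NULL)
      data.frame(status = st, sex = sx, lmp2 = NA_character_,
                 a02_carrier = "unknown", stringsAsFactors = FALSE)[rep(1, need), ]
    }))
  }))
  out <- rbind(genotyped, filler)
  out$subject_id <- sprintf("MS%04d", seq_len(nrow(out)))
  out$drb115_carrier <- "unknown"
  out$onset_age <- NA_real_
  out$cohort <- ifelse(out$status == "case", "pooled", "control")
  rownames(out) <- NULL
  out[, c("subject_id", "status", "sex", "lmp2", "a02_carrier",
          "drb115_carrier", "onset_age", "cohort")]
}
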