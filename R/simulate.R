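#' Configuration for the genotype population generator
#'
#' Collects and validates the parameters of the synthetic case-control
#' population: allele/carrier frequencies, the logistic disease model, and the
#' seed. Disease status is drawn from a logistic model on the log-odds scale:
#' the baseline log-odds plus the log of each applicable odds ratio. The
#' LMP2 codon-60 genotype is drawn from Hardy-Weinberg proportions of
#' `h_allele_freq`, and the HH odds ratio applies only within the
#' female x HLA-A*02-carrier stratum, mirroring the stratum-specific effect
#' the association pipeline is designed to detect.
#'
#' Default effect sizes are the study conditions of the analysis this package
#' reproduces: OR(HLA-A*02) = 0.671, OR(HLA-DRB1*15) = 2.525, and
#' OR(LMP2 60HH vs others, female A*02 carriers) = 0.443.
#'
#' @param n_subjects number of subjects to draw.
#' @param h_allele_freq population frequency of the LMP2 60H allele.
#' @param a02_carrier_freq probability of carrying HLA-A*02.
#' @param drb115_carrier_freq probability of carrying HLA-DRB1*15.
#' @param female_freq probability of female sex.
#' @param baseline_case_logodds intercept of the logistic disease model.
#' @param or_drb115,or_a02 marginal carrier odds ratios (> 0).
#' @param or_hh_in_a02_females odds ratio of the HH genotype applied only to
#'   female HLA-A*02 carriers (> 0).
#' @param seed master seed; all stage seeds are derived from it.
#' @return an object of class `genotype_sim_config`.
#' @seealso [simulate_population()]
#' @export
genotype_sim_config <- function(n_subjects,
                                h_allele_freq = 0.356,
                                a02_carrier_freq = 0.5,
                                drb115_carrier_freq = 0.2,
                                female_freq = 0.5,
                                baseline_case_logodds = -1,
                                or_drb115 = 2.525,
                                or_a02 = 0.671,
                                or_hh_in_a02_females = 0.443,
                                seed = 1L) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  check_prob(h_allele_freq, "h_allele_freq")
  check_prob(a02_carrier_freq, "a02_carrier_freq")
  check_prob(drb115_carrier_freq, "drb115_carrier_freq")
  check_prob(female_freq, "female_freq")
  if (!is.numeric(baseline_case_logodds) || !is.finite(baseline_case_logodds)) {
    stop("'baseline_case_logodds' must be a finite number", call. = FALSE)
  }
  check_pos(or_drb115, "or_drb115")
  check_pos(or_a02, "or_a02")
  check_pos(or_hh_in_a02_females, "or_hh_in_a02_females")
  cfg <- list(n_subjects = n_subjects,
              h_allele_freq = h_allele_freq,
              a02_carrier_freq = a02_carrier_freq,
              drb115_carrier_freq = drb115_carrier_freq,
              female_freq = female_freq,
              baseline_case_logodds = baseline_case_logodds,
              or_drb115 = or_drb115,
              or_a02 = or_a02,
              or_hh_in_a02_females = or_hh_in_a02_females,
              seed = as.integer(seed))
  class(cfg) <- "genotype_sim_config"
  cfg
}

#' Simulate a genotyped case-control population
#'
#' Draws independent subjects: sex, HLA-A*02 and HLA-DRB1*15 carriage,
#' LMP2 codon-60 genotype under Hardy-Weinberg equilibrium, then disease
#' status from the logistic model in the configuration. Cases receive a
#' simulated onset age (normal, mean 30.5 y, SD 10 y, floored at 18) and a
#' random cohort label ("1"/"2"); controls get cohort "control".
#'
#' @param config a [genotype_sim_config()].
#' @return a data.frame with columns `subject_id`, `status`, `sex`, `lmp2`,
#'   `a02_carrier`, `drb115_carrier`, `onset_age`, `cohort`, with the
#'   generating configuration attached as attribute `"ground_truth"`.
#' @examples
#' subj <- simulate_population(genotype_sim_config(500, seed = 42))
#' table(subj$status, subj$lmp2)
#' @export
simulate_population <- function(config) {
  if (!inherits(config, "genotype_sim_config")) {
    stop("'config' must be created by genotype_sim_config()", call. = FALSE)
  }
  n <- config$n_subjects
  set.seed(substream_seed(config$seed, 1L))
  sex <- ifelse(stats::runif(n) < config$female_freq, "female", "male")
  a02 <- ifelse(stats::runif(n) < config$a02_carrier_freq, "yes", "no")
  drb <- ifelse(stats::runif(n) < config$drb115_carrier_freq, "yes", "no")
  h <- config$h_allele_freq
  gprob <- c(HH = h^2, RH = 2 * h * (1 - h), RR = (1 - h)^2)
  lmp2 <- sample(names(gprob), n, replace = TRUE, prob = gprob)
  logodds <- config$baseline_case_logodds +
    log(config$or_drb115) * (drb == "yes") +
    log(config$or_a02) * (a02 == "yes") +
    log(config$or_hh_in_a02_females) *
      (lmp2 == "HH" & sex == "female" & a02 == "yes")
  status <- ifelse(stats::runif(n) < stats::plogis(logodds), "case", "control")

  set.seed(substream_seed(config$seed, 2L))
  onset <- pmax(18, round(stats::rnorm(n, mean = 30.5, sd = 10), 1))
  onset[status != "case"] <- NA_real_
  cohort <- ifelse(status == "case",
                   sample(c("1", "2"), n, replace = TRUE), "control")

  out <- data.frame(subject_id = sprintf("S%06d", seq_len(n)),
                    status = status, sex = sex, lmp2 = lmp2,
                    a02_carrier = a02, drb115_carrier = drb,
                    onset_age = onset, cohort = cohort,
                    stringsAsFactors = FALSE)
  attr(out, "ground_truth") <- unclass(config)
  out
}

#' Configuration for the digestion time-course generator
#'
#' Parameters of the synthetic in-vitro digestion of the 28-mer myelin basic
#' protein substrate (MBP 102-129, PSQGKGRGLSLSRFSWGAEGQRPGFGYG) by purified
#' 20S immunoproteasome preparations with and without the PA28-alpha/beta
#' activator. The substrate signal decays as a first-order reaction,
#' S(t) = B * s0 * exp(-K1 * t), with K1 = `k1_base` multiplied by
#' `k1_pa28_multiplier` when PA28 is present. Each tiled fragment (1-9,
#' 10-18 = the MBP 111-119 epitope, 19-28) accumulates in proportion to the
#' substrate consumed, F(t) = B * yield * (s0 - s0 * exp(-K1 * t)) * eps,
#' where B is a per-set lognormal detector/batch factor and eps per-signal
#' multiplicative lognormal noise. When PA28 is present, the epitope yield of
#' H-carrier preparations (RH or HH) is multiplied by `h_carrier_yield_ratio`,
#' the effect the SP pipeline is designed to recover.
#'
#' Defaults give both PA28 conditions time points in each substrate-consumption
#' bin (<25%, 25-35%, 35-50%) plus excluded (>=50%) points.
#'
#' @param n_preparations_per_genotype named counts of preparations per LMP2
#'   genotype, default `c(RR = 3, RH = 3, HH = 3)`.
#' @param k1_base first-order rate constant without PA28, per minute.
#' @param k1_pa28_multiplier fold acceleration of K1 by PA28 (> 1).
#' @param epitope_yield_base epitope molecules per consumed substrate, in
#'   \[0, 1\].
#' @param h_carrier_yield_ratio multiplier in (0, 1\] applied to the epitope
#'   yield of RH/HH preparations when PA28 is present.
#' @param flanking_yield_1_9,flanking_yield_19_28 yields of the two flanking
#'   fragments, in \[0, 1\].
#' @param timepoints_min strictly increasing sampling times in minutes; the
#'   first must be 0 (the SP denominator needs the time-zero signal).
#' @param batch_scale_sd lognormal sigma of the per-set detector factor.
#' @param noise_sd lognormal sigma of per-signal multiplicative noise.
#' @param s0 true initial substrate signal in detector units.
#' @param seed master seed.
#' @return an object of class `digestion_sim_config`.
#' @seealso [simulate_digestion()]
#' @export
digestion_sim_config <- function(n_preparations_per_genotype = c(RR = 3, RH = 3, HH = 3),
                                 k1_base = 0.002,
                                 k1_pa28_multiplier = 2,
                                 epitope_yield_base = 0.30,
                                 h_carrier_yield_ratio = 0.712,
                                 flanking_yield_1_9 = 0.35,
                                 flanking_yield_19_28 = 0.30,
                                 timepoints_min = c(0, 15, 30, 60, 90, 120, 180, 240, 300),
                                 batch_scale_sd = 0.3,
                                 noise_sd = 0.15,
                                 s0 = 1000,
                                 seed = 1L) {
  if (is.null(names(n_preparations_per_genotype)) ||
      !setequal(names(n_preparations_per_genotype), c("RR", "RH", "HH"))) {
    stop("'n_preparations_per_genotype' must be named with RR, RH, HH",
         call. = FALSE)
  }
  if (any(n_preparations_per_genotype < 0) ||
      any(n_preparations_per_genotype != floor(n_preparations_per_genotype)) ||
      sum(n_preparations_per_genotype) < 1) {
    stop("preparation counts must be non-negative integers, at least one > 0",
         call. = FALSE)
  }
  check_pos(k1_base, "k1_base")
  if (!is.numeric(k1_pa28_multiplier) || k1_pa28_multiplier <= 1) {
    stop("'k1_pa28_multiplier' must be > 1", call. = FALSE)
  }
  check_prob(epitope_yield_base, "epitope_yield_base")
  if (!is.numeric(h_carrier_yield_ratio) || h_carrier_yield_ratio <= 0 ||
      h_carrier_yield_ratio > 1) {
    stop("'h_carrier_yield_ratio' must be in (0, 1]", call. = FALSE)
  }
  check_prob(flanking_yield_1_9, "flanking_yield_1_9")
  check_prob(flanking_yield_19_28, "flanking_yield_19_28")
  if (length(timepoints_min) < 3 || any(diff(timepoints_min) <= 0)) {
    stop("'timepoints_min' must be a strictly increasing vector of length >= 3",
         call. = FALSE)
  }
  if (timepoints_min[1] != 0) {
    stop("'timepoints_min' must start at 0", call. = FALSE)
  }
  check_pos(batch_scale_sd, "batch_scale_sd", strict = FALSE)
  check_pos(noise_sd, "noise_sd", strict = FALSE)
  check_pos(s0, "s0")
  cfg <- list(n_preparations_per_genotype =
                n_preparations_per_genotype[c("RR", "RH", "HH")],
              k1_base = k1_base,
              k1_pa28_multiplier = k1_pa28_multiplier,
              epitope_yield_base = epitope_yield_base,
              h_carrier_yield_ratio = h_carrier_yield_ratio,
              flanking_yield_1_9 = flanking_yield_1_9,
              flanking_yield_19_28 = flanking_yield_19_28,
              timepoints_min = as.numeric(timepoints_min),
              batch_scale_sd = batch_scale_sd,
              noise_sd = noise_sd,
              s0 = s0,
              seed = as.integer(seed))
  class(cfg) <- "digestion_sim_config"
  cfg
}

#' The 28-mer substrate and its tiled fragments
#'
#' The digestion substrate MBP 102-129 and the 1-based coordinates of the
#' three tiled fragments quantified by the pipeline; fragment 10-18 is the
#' HLA-A*0201-restricted epitope MBP 111-119 (SLSRFSWGA).
#'
#' @return a list with `substrate_sequence` and `fragment_coords`.
#' @export
mbp_substrate <- function() {
  list(substrate_sequence = "PSQGKGRGLSLSRFSWGAEGQRPGFGYG",
       fragment_coords = list(frag_1_9 = c(1L, 9L),
                              frag_10_18 = c(10L, 18L),
                              frag_19_28 = c(19L, 28L)))
}

#' Simulate immunoproteasome digestion time-courses
#'
#' Generates one degradation set per preparation x PA28 condition: a
#' substrate decay curve and the three fragment accumulation curves under the
#' model described in [digestion_sim_config()]. Fragment signals are zero at
#' time 0. True per-set parameters (K1, yields, batch factor) are recorded in
#' the `"ground_truth"` attribute.
#'
#' @param config a [digestion_sim_config()].
#' @return a data.frame with columns `set_id`, `preparation_id`, `genotype`,
#'   `pa28` ("present"/"absent"), `time_min`, `substrate_signal`, `frag_1_9`,
#'   `frag_10_18`, `frag_19_28`.
#' @examples
#' dig <- simulate_digestion(digestion_sim_config(seed = 7))
#' head(dig)
#' @export
simulate_digestion <- function(config) {
  if (!inherits(config, "digestion_sim_config")) {
    stop("'config' must be created by digestion_sim_config()", call. = FALSE)
  }
  counts <- config$n_preparations_per_genotype
  genotype <- rep(names(counts), counts)
  prep_id <- sprintf("P%02d", seq_along(genotype))
  tp <- config$timepoints_min
  frag_names <- c("frag_1_9", "frag_10_18", "frag_19_28")

  set.seed(substream_seed(config$seed, 1L))
  rows <- vector("list", 2L * length(prep_id))
  truth <- vector("list", 2L * length(prep_id))
  r <- 0L
  for (i in seq_along(prep_id)) {
    for (pa28 in c("present", "absent")) {
      r <- r + 1L
      k1 <- config$k1_base *
        if (pa28 == "present") config$k1_pa28_multiplier else 1
      yields <- c(frag_1_9 = config$flanking_yield_1_9,
                  frag_10_18 = config$epitope_yield_base,
                  frag_19_28 = config$flanking_yield_19_28)
      if (pa28 == "present" && genotype[i] %in% c("RH", "HH")) {
        yields["frag_10_18"] <- yields["frag_10_18"] *
          config$h_carrier_yield_ratio
      }
      batch <- stats::rlnorm(1, 0, config$batch_scale_sd)
      substrate <- batch * config$s0 * exp(-k1 * tp)
      consumed <- config$s0 * (1 - exp(-k1 * tp))
      eps <- matrix(stats::rlnorm(length(tp) * 3L, 0, config$noise_sd),
                    nrow = length(tp), ncol = 3L)
      frags <- batch * (consumed %o% yields) * eps
      set_id <- sprintf("%s_%s", prep_id[i],
                        if (pa28 == "present") "pa28" else "core")
      df <- data.frame(set_id = set_id, preparation_id = prep_id[i],
                       genotype = genotype[i], pa28 = pa28, time_min = tp,
                       substrate_signal = substrate,
                       stringsAsFactors = FALSE)
      df[frag_names] <- frags
      rows[[r]] <- df
      truth[[r]] <- list(set_id = set_id, genotype = genotype[i],
                         pa28 = pa28, k1 = k1, batch = batch,
                         yields = as.list(yields))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ground_truth") <- list(config = unclass(config), sets = truth)
  out
}
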