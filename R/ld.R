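#' EM haplotype-frequency estimation for two unphased biallelic loci
#'
#' Maximum-likelihood haplotype frequencies (p_AB, p_Ab, p_aB, p_ab) from
#' unphased two-locus genotypes. Only double heterozygotes have ambiguous
#' phase; the E-step splits them between the AB|ab and Ab|aB configurations
#' in proportion to the current haplotype-frequency products, the M-step
#' recounts haplotypes. Iteration starts from linkage-equilibrium frequencies
#' and stops when the log-likelihood improves by less than `tol` (default
#' 1e-10) or after `max_iter` iterations. The log-likelihood is checked to be
#' non-decreasing at every step.
#'
#' Genotypes are given as allele counts 0/1/2 (copies of allele A at locus 1,
#' of allele B at locus 2) or as strings `"aa"/"Aa"/"AA"` and
#' `"bb"/"Bb"/"BB"`. Carrier-status loci typed at presence/absence resolution
#' can be coded dominantly (carrier = 1 copy).
#'
#' @param geno1,geno2 per-subject genotypes at the two loci.
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @return an object of class `ld_estimate`: `hap_freqs` (named numeric),
#'   `d`, `d_prime`, `r2`, `log_likelihood`, `n_iterations`, `converged`,
#'   `n` (subjects used), `chi2`, `p` (LD chi-squared on 2n chromosomes,
#'   df = 1).
#' @examples
#' g1 <- c(rep(2, 50), rep(0, 50))
#' em_haplotype_freqs(g1, g1)  # complete LD: D' = 1, r2 = 1
#' @export
em_haplotype_freqs <- function(geno1, geno2, tol = 1e-10, max_iter = 1000) {
  g1 <- geno_to_count(geno1, c("a", "A"))
  g2 <- geno_to_count(geno2, c("b", "B"))
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]
  g2 <- g2[keep]
  n <- length(g1)
  if (n < 2) stop("need >= 2 subjects with both genotypes", call. = FALSE)
  pa <- sum(g1) / (2 * n)
  pb <- sum(g2) / (2 * n)
  if (pa %in% c(0, 1) || pb %in% c(0, 1) ||
      length(unique(g1)) == 1L || length(unique(g2)) == 1L) {
    stop("undefined LD: at least one locus is monomorphic (no genotype variation)",
         call. = FALSE)
  }
  # 3x3 genotype counts, rows = copies of A (0,1,2), cols = copies of B
  cnt <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    cnt[g1[i] + 1, g2[i] + 1] <- cnt[g1[i] + 1, g2[i] + 1] + 1
  }
  # unambiguous haplotype counts contributed by all cells except double hets
  base <- c(AB = 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3],
            Ab = 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1],
            aB = 2 * cnt[1, 3] + cnt[1, 2] + cnt[2, 3],
            ab = 2 * cnt[1, 1] + cnt[1, 2] + cnt[2, 1])
  ndh <- cnt[2, 2]

  p <- c(AB = pa * pb, Ab = pa * (1 - pb), aB = (1 - pa) * pb,
         ab = (1 - pa) * (1 - pb))
  ll <- genotype_loglik(cnt, p)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    denom <- p["AB"] * p["ab"] + p["Ab"] * p["aB"]
    w <- if (denom > 0) unname(p["AB"] * p["ab"] / denom) else 0.5
    hap <- base + ndh * c(w, 1 - w, 1 - w, w)
    p_new <- hap / (2 * n)
    ll_new <- genotype_loglik(cnt, p_new)
    if (ll_new < ll - 1e-9) {
      stop("internal error: EM log-likelihood decreased", call. = FALSE)
    }
    p <- p_new
    if (ll_new - ll < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  stats <- ld_stats(p)
  chi2 <- 2 * n * stats$r2
  structure(list(hap_freqs = p, d = stats$d, d_prime = stats$d_prime,
                 r2 = stats$r2, log_likelihood = ll, n_iterations = iter,
                 converged = converged, n = n, chi2 = chi2,
                 p = stats::pchisq(chi2, 1, lower.tail = FALSE)),
            class = "ld_estimate")
}

#' @export
print.ld_estimate <- function(x, ...) {
  cat(sprintf("LD estimate (n = %d): D = %.4f, D' = %.3f, r2 = %.4g, p = %.3g\n",
              x$n, x$d, x$d_prime, x$r2, x$p))
  cat(sprintf("  haplotype freqs: AB %.4f, Ab %.4f, aB %.4f, ab %.4f (logLik %.6f, %d EM iterations)\n",
              x$hap_freqs["AB"], x$hap_freqs["Ab"], x$hap_freqs["aB"],
              x$hap_freqs["ab"], x$log_likelihood, x$n_iterations))
  invisible(x)
}

#' Linkage-disequilibrium statistics from haplotype frequencies
#'
#' `D = p_AB - p_A p_B`; Lewontin's `D' = D / D_max` with
#' `D_max = min(p_A p_b, p_a p_B)` for D > 0 and `min(p_A p_B, p_a p_b)` for
#' D < 0 (D' = 0 when D = 0); `r2 = D^2 / (p_A p_a p_B p_b)`.
#'
#' @param hap_freqs numeric vector (p_AB, p_Ab, p_aB, p_ab) summing to 1.
#' @return list with `d`, `d_prime`, `r2`.
#' @examples
#' ld_stats(c(0.4, 0.1, 0.2, 0.3))  # D = 0.10, D' = 0.5, r2 ~ 0.1667
#' @export
ld_stats <- function(hap_freqs) {
  p <- as.numeric(hap_freqs)
  if (length(p) != 4 || any(p < -1e-12) || abs(sum(p) - 1) > 1e-8) {
    stop("'hap_freqs' must be 4 non-negative frequencies summing to 1",
         call. = FALSE)
  }
  p <- pmax(p, 0)
  pab_ <- p  # (AB, Ab, aB, ab)
  pa <- pab_[1] + pab_[2]
  pb <- pab_[1] + pab_[3]
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1) {
    stop("undefined LD: boundary allele frequency", call. = FALSE)
  }
  d <- pab_[1] - pa * pb
  if (abs(d) < 1e-15) {
    dp <- 0
  } else if (d > 0) {
    dp <- d / min(pa * (1 - pb), (1 - pa) * pb)
  } else {
    dp <- d / min(pa * pb, (1 - pa) * (1 - pb))
  }
  r2 <- d^2 / (pa * (1 - pa) * pb * (1 - pb))
  list(d = d, d_prime = dp, r2 = r2)
}

# multinomial log-likelihood of a 3x3 unphased genotype count table given
# haplotype frequencies p = (AB, Ab, aB, ab)
genotype_loglik <- function(cnt, p) {
  pr <- matrix(0, 3, 3)
  pr[3, 3] <- p["AB"]^2
  pr[3, 2] <- 2 * p["AB"] * p["Ab"]
  pr[3, 1] <- p["Ab"]^2
  pr[2, 3] <- 2 * p["AB"] * p["aB"]
  pr[2, 2] <- 2 * (p["AB"] * p["ab"] + p["Ab"] * p["aB"])
  pr[2, 1] <- 2 * p["Ab"] * p["ab"]
  pr[1, 3] <- p["aB"]^2
  pr[1, 2] <- 2 * p["aB"] * p["ab"]
  pr[1, 1] <- p["ab"]^2
  use <- cnt > 0
  sum(cnt[use] * log(pr[use]))
}

geno_to_count <- function(g, alleles) {
  if (is.numeric(g)) {
    if (any(!(g %in% c(0, 1, 2)) & !is.na(g))) {
      stop("numeric genotypes must be allele counts 0, 1 or 2", call. = FALSE)
    }
    return(as.integer(g))
  }
  lo <- alleles[1]
  hi <- alleles[2]
  map <- stats::setNames(c(0L, 1L, 1L, 2L),
                         c(paste0(lo, lo), paste0(hi, lo), paste0(lo, hi),
                           paste0(hi, hi)))
  out <- map[as.character(g)]
  if (any(is.na(out) & !is.na(g))) {
    stop("unrecognized genotype strings", call. = FALSE)
  }
  unname(out)
}

#' Dominant (carrier) coding of a presence/absence locus
#'
#' Loci typed only at carrier resolution (e.g. HLA-A*02 carried yes/no) are
#' coded as biallelic markers with carriers assigned one copy of the allele
#' and non-carriers none.
#'
#' @param carrier character vector of `"yes"`/`"no"` (others become NA).
#' @return integer allele counts (1, 0, NA).
#' @export
carrier_to_count <- function(carrier) {
  out <- rep(NA_integer_, length(carrier))
  out[carrier == "yes"] <- 1L
  out[carrier == "no"] <- 0L
  out
}

#' LMP2 genotype to H-allele count
#'
#' @param lmp2 character vector of `"RR"/"RH"/"HH"` (others become NA).
#' @return integer counts of the H allele (0, 1, 2, NA).
#' @export
lmp2_to_count <- function(lmp2) {
  map <- c(RR = 0L, RH = 1L, HH = 2L)
  unname(map[as.character(lmp2)])
}
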