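# Independent oracles used to check the implementation. These deliberately
# use brute force (grids, full enumeration) and share no code with R/.

# Brute-force least-squares fit of log S(t) = log S0 - K1 t over a (K1, S0)
# grid. Returns the grid point with the smallest sum of squared log residuals.
grid_k1_oracle <- function(time, signal, k1_range, s0_range,
                           n_grid = 200) {
  k1s <- seq(k1_range[1], k1_range[2], length.out = n_grid)
  s0s <- seq(s0_range[1], s0_range[2], length.out = n_grid)
  keep <- signal > 0
  t <- time[keep]
  y <- log(signal[keep])
  best <- c(k1 = NA, s0 = NA, sse = Inf)
  for (k1 in k1s) {
    # residuals for all s0 at once
    pred0 <- -k1 * t
    for (s0 in s0s) {
      sse <- sum((y - (log(s0) + pred0))^2)
      if (sse < best["sse"]) best <- c(k1 = k1, s0 = s0, sse = sse)
    }
  }
  best
}

# Exact two-sided p of the Pearson statistic for a 2x2 table with fixed
# margins, by full enumeration of the hypergeometric distribution of cell a.
enum_chi2_p_2x2 <- function(tab) {
  rs <- rowSums(tab)
  cs <- colSums(tab)
  n <- sum(tab)
  chi2_of <- function(a) {
    m <- matrix(c(a, rs[1] - a, cs[1] - a, n - rs[1] - cs[1] + a), 2, 2)
    e <- outer(rs, cs) / n
    sum((m - e)^2 / e)
  }
  obs <- chi2_of(tab[1, 1])
  as <- max(0, rs[1] + cs[1] - n):min(rs[1], cs[1])
  probs <- stats::dhyper(as, cs[1], n - cs[1], rs[1])
  chis <- vapply(as, chi2_of, numeric(1))
  sum(probs[chis >= obs - 1e-9])
}

# One-way F statistic, written independently of the package.
oracle_f <- function(x, g) {
  g <- as.factor(g)
  fit <- stats::oneway.test(x ~ g, var.equal = TRUE)
  unname(fit$statistic)
}

# Exhaustive two-group permutation p of the F statistic via combn.
enum_perm_f_p_2g <- function(x, n1) {
  n <- length(x)
  idx <- utils::combn(n, n1)
  g_obs <- c(rep("a", n1), rep("b", n - n1))
  f_obs <- oracle_f(x, g_obs)
  f_all <- apply(idx, 2, function(i) {
    g <- rep("b", n)
    g[i] <- "a"
    oracle_f(x, g)
  })
  mean(f_all >= f_obs - 1e-9)
}

# Exhaustive three-group permutation p of F via nested combn.
enum_perm_f_p_3g <- function(x, sizes) {
  n <- length(x)
  g_obs <- rep(c("a", "b", "c"), sizes)
  f_obs <- oracle_f(x, g_obs)
  count <- 0L
  total <- 0L
  first <- utils::combn(n, sizes[1])
  for (j in seq_len(ncol(first))) {
    rest <- setdiff(seq_len(n), first[, j])
    second <- utils::combn(rest, sizes[2])
    for (l in seq_len(ncol(second))) {
      g <- rep("c", n)
      g[first[, j]] <- "a"
      g[second[, l]] <- "b"
      total <- total + 1L
      if (oracle_f(x, g) >= f_obs - 1e-9) count <- count + 1L
    }
  }
  count / total
}

# Multinomial log-likelihood of unphased two-locus genotype data on a 1-D
# grid over p_AB, with allele frequencies held at their sample values (allele
# counts are phase-invariant, so the MLE lies on that slice).
ld_grid_loglik_max <- function(g1, g2, step = 1e-6) {
  n <- length(g1)
  pa <- sum(g1) / (2 * n)
  pb <- sum(g2) / (2 * n)
  lo <- max(0, pa + pb - 1)
  hi <- min(pa, pb)
  pab <- unique(c(lo, seq(lo, hi, by = step), hi))
  p_ab_ <- cbind(AB = pab, Ab = pa - pab, aB = pb - pab, ab = 1 - pa - pb + pab)
  p_ab_ <- pmax(p_ab_, 0)  # guard tiny negative values at the endpoints
  cnt <- table(factor(g1, 0:2), factor(g2, 0:2))
  # genotype-class probabilities; cells with zero count contribute nothing,
  # even at boundary haplotype frequencies where their probability is 0
  term <- function(count, prob) {
    if (count == 0) return(rep(0, length(prob)))
    count * log(prob)
  }
  ll <- term(cnt["2", "2"], p_ab_[, "AB"]^2) +
    term(cnt["2", "1"], 2 * p_ab_[, "AB"] * p_ab_[, "Ab"]) +
    term(cnt["2", "0"], p_ab_[, "Ab"]^2) +
    term(cnt["1", "2"], 2 * p_ab_[, "AB"] * p_ab_[, "aB"]) +
    term(cnt["1", "1"], 2 * (p_ab_[, "AB"] * p_ab_[, "ab"] +
                               p_ab_[, "Ab"] * p_ab_[, "aB"])) +
    term(cnt["1", "0"], 2 * p_ab_[, "Ab"] * p_ab_[, "ab"]) +
    term(cnt["0", "2"], p_ab_[, "aB"]^2) +
    term(cnt["0", "1"], 2 * p_ab_[, "aB"] * p_ab_[, "ab"]) +
    term(cnt["0", "0"], p_ab_[, "ab"]^2)
  max(ll)
}

# Random two-locus genotype sample with a configurable haplotype distribution.
random_genotype_pairs <- function(n, hap_freqs) {
  haps <- matrix(sample(4, 2 * n, replace = TRUE, prob = hap_freqs), ncol = 2)
  a_of <- c(1, 1, 0, 0)  # AB, Ab, aB, ab
  b_of <- c(1, 0, 1, 0)
  list(g1 = a_of[haps[, 1]] + a_of[haps[, 2]],
       g2 = b_of[haps[, 1]] + b_of[haps[, 2]])
}

# Noiseless digestion config shortcut.
noiseless_config <- function(...) {
  digestion_sim_config(batch_scale_sd = 0, noise_sd = 0, ...)
}
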