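# Internal helpers shared across modules.

# Derive a reproducible substream seed from a master seed and a stage counter,
# so individual pipeline stages can be re-run independently. Kept inside
# 32-bit integer range (Lehmer-style mix modulo the Mersenne prime 2^31-1).
substream_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(k), length(k) == 1L)
  m <- 2147483647
  s <- (abs(as.double(seed)) %% m) + 1
  for (i in seq_len(as.integer(k) + 1L)) {
    s <- (s * 48271) %% m
  }
  as.integer(s %% .Machine$integer.max)
}

# Numeric tolerance used when counting permutation statistics >= observed,
# so the identity permutation always counts despite floating-point noise.
stat_ge <- function(sim, obs) {
  if (!is.finite(obs)) {
    return(sim >= obs)
  }
  sim >= obs - 1e-8 * max(1, abs(obs))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

check_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > 0 else x >= 0) && is.finite(x)
  if (!ok) {
    stop(sprintf("'%s' must be a single finite %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
      x != floor(x)) {
    stop(sprintf("'%s' must be a positive integer", name), call. = FALSE)
  }
  invisible(as.integer(x))
}

# One-way ANOVA F statistic with explicit handling of degenerate variance:
# zero total variance -> F = 0; zero within-group variance with between-group
# spread -> F = Inf.
f_statistic <- function(x, g) {
  g <- as.factor(g)
  n <- length(x)
  k <- nlevels(g)
  gm <- mean(x)
  means <- tapply(x, g, mean)
  sizes <- tapply(x, g, length)
  ssb <- sum(sizes * (means - gm)^2)
  ssw <- sum((x - means[g])^2)
  if (ssb + ssw <= 1e-12 * max(1, gm^2)) {
    return(0)
  }
  if (ssw == 0) {
    return(Inf)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

# All distinct assignments of observations to groups of the given sizes,
# returned as an integer matrix (n rows, one column per assignment, entries
# are group indices). Sizes are taken in order; the count is the multinomial
# coefficient.
enumerate_assignments <- function(sizes) {
  n <- sum(sizes)
  if (length(sizes) == 1L) {
    return(matrix(1L, nrow = n, ncol = 1L))
  }
  first <- utils::combn(n, sizes[1])
  sub <- enumerate_assignments(sizes[-1]) + 1L
  out <- vector("list", ncol(first))
  for (j in seq_len(ncol(first))) {
    idx <- first[, j]
    block <- matrix(0L, nrow = n, ncol = ncol(sub))
    block[idx, ] <- 1L
    block[-idx, ] <- sub
    out[[j]] <- block
  }
  do.call(cbind, out)
}

n_assignments <- function(sizes) {
  exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
}

round1 <- function(x) round(x, 1)
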