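#' Specific Production of a fragment
#'
#' SP = 1000 * (fragment signal) / (signal of substrate degraded). Because
#' fragment and substrate are read in the same detector channel, the per-set
#' scale factor cancels and SP estimates the amount of fragment produced per
#' unit of consumed substrate. The factor 1000 is cosmetic.
#'
#' @param fragment_signal quantified fragment signal(s), >= 0.
#' @param substrate_consumed_signal signal of substrate degraded,
#'   `S(0) - S(t)`, must be > 0.
#' @return SP value(s).
#' @examples
#' compute_sp(50, 200)  # 250
#' @export
compute_sp <- function(fragment_signal, substrate_consumed_signal) {
  if (any(!is.finite(substrate_consumed_signal)) ||
      any(substrate_consumed_signal <= 0)) {
    stop("SP undefined: consumed-substrate signal must be > 0", call. = FALSE)
  }
  if (any(fragment_signal < 0)) {
    stop("fragment signal must be >= 0", call. = FALSE)
  }
  1000 * fragment_signal / substrate_consumed_signal
}

#' Consumption bin of a digestion sample
#'
#' Samples are grouped by the fraction of substrate consumed so that only
#' samples with similar degradation are compared: \[0, 0.25) -> `lt25`,
#' \[0.25, 0.35) -> `b25_35`, \[0.35, 0.50) -> `b35_50`. Samples with >= 50%
#' consumption are `excluded` from comparisons (product re-entry into the
#' proteasome core distorts quantification beyond that point).
#'
#' @param consumption fraction(s) of substrate consumed, in \[0, 1\].
#' @return factor with levels `lt25`, `b25_35`, `b35_50`, `excluded`.
#' @export
assign_bin <- function(consumption) {
  if (any(!is.finite(consumption)) || any(consumption < 0) ||
      any(consumption > 1)) {
    stop("consumption must be in [0, 1]", call. = FALSE)
  }
  cut(consumption, breaks = c(0, 0.25, 0.35, 0.50, 1 + 1e-9),
      labels = c("lt25", "b25_35", "b35_50", "excluded"),
      right = FALSE, include.lowest = TRUE)
}

#' SP estimates for every fragment x time point of a digestion table
#'
#' For each degradation set, computes the consumed-substrate signal
#' `S(0) - S(t)` at every positive time point, the SP of each tiled fragment,
#' the fraction consumed and its bin. Time points where no substrate has been
#' consumed (consumed signal <= 0, possible under noise) are dropped with a
#' warning, since SP is undefined there.
#'
#' @param digestion digestion data.frame in the standard long format.
#' @param fragments fragment columns to evaluate.
#' @return a data.frame with columns `set_id`, `preparation_id`, `genotype`,
#'   `pa28`, `fragment`, `time_min`, `sp`, `consumption`, `bin`.
#' @examples
#' dig <- simulate_digestion(digestion_sim_config(seed = 3))
#' head(sp_estimates(dig))
#' @export
sp_estimates <- function(digestion,
                         fragments = c("frag_1_9", "frag_10_18", "frag_19_28")) {
  check_digestion(digestion)
  sets <- split(digestion, digestion$set_id)
  out <- lapply(sets, function(d) {
    i0 <- which(d$time_min == 0)
    if (length(i0) != 1L || !(d$substrate_signal[i0] > 0)) {
      stop(sprintf("set '%s' lacks a positive substrate signal at time 0",
                   d$set_id[1]), call. = FALSE)
    }
    dt <- d[d$time_min > 0, , drop = FALSE]
    consumed <- d$substrate_signal[i0] - dt$substrate_signal
    usable <- consumed > 0
    if (any(!usable)) {
      warning(sprintf("set '%s': dropped %d time point(s) with no measurable consumption",
                      d$set_id[1], sum(!usable)))
    }
    dt <- dt[usable, , drop = FALSE]
    consumed <- consumed[usable]
    if (nrow(dt) == 0) return(NULL)
    consumption <- fraction_consumed(d$time_min, d$substrate_signal,
                                     at = dt$time_min)
    blocks <- lapply(fragments, function(fr) {
      data.frame(set_id = dt$set_id, preparation_id = dt$preparation_id,
                 genotype = dt$genotype, pa28 = dt$pa28, fragment = fr,
                 time_min = dt$time_min,
                 sp = compute_sp(dt[[fr]], consumed),
                 consumption = consumption,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, blocks)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$bin <- assign_bin(res$consumption)
  res
}

#' Standardize SP values within degradation sets
#'
#' Mass-spectrometry signals from different experiments are on different
#' detector scales; to compare them across sets, SP values are z-scored
#' within each `set_id` x `fragment` group using the sample (n - 1) standard
#' deviation. Raw SP is preserved. Groups with fewer than 2 values or zero
#' variance are flagged and passed through unstandardized with a warning.
#'
#' @param estimates data.frame from [sp_estimates()].
#' @return the input with columns `sp_standardized` and `standardized`
#'   (logical flag) added.
#' @export
standardize_within_set <- function(estimates) {
  stopifnot(all(c("set_id", "fragment", "sp") %in% names(estimates)))
  key <- interaction(estimates$set_id, estimates$fragment, drop = TRUE)
  m <- tapply(estimates$sp, key, mean)
  s <- tapply(estimates$sp, key, stats::sd)
  n <- tapply(estimates$sp, key, length)
  # variance at floating-point noise level counts as zero
  ok <- !is.na(s) & s > 1e-8 * (abs(m) + 1) & n >= 2
  if (any(!ok)) {
    warning(sprintf("%d set x fragment group(s) with < 2 values or zero variance passed through unstandardized",
                    sum(!ok)))
  }
  z <- ifelse(ok[key],
              (estimates$sp - m[key]) / s[key],
              estimates$sp)
  estimates$sp_standardized <- as.numeric(z)
  estimates$standardized <- as.logical(ok[key])
  estimates
}

#' Genotype effect on SP within one consumption bin
#'
#' Restricts SP estimates to one fragment, consumption bin and PA28 condition
#' and tests the LMP2 genotype effect either as a two-group pooled-variance
#' Student t of H-carriers (RH + HH) versus non-carriers (RR), preceded by a
#' recorded Levene check, or as a permutation F across the three genotypes.
#' The percent decrease `100 * (1 - mean(H-carrier) / mean(non-carrier))` is
#' always computed from unstandardized SP so that it reads as a yield ratio.
#'
#' @param estimates data.frame from [sp_estimates()] (optionally after
#'   [standardize_within_set()]).
#' @param fragment fragment to test (default the epitope, `frag_10_18`).
#' @param bin one of `"lt25"`, `"b25_35"`, `"b35_50"`.
#' @param pa28 `"present"` or `"absent"`.
#' @param mode `"h_carrier_t"` (pooled-variance Student t, two-sided) or
#'   `"three_group_mc_anova"` (permutation F across RR/RH/HH).
#' @param use_standardized compare `sp_standardized` instead of raw `sp`
#'   (the percent decrease is still computed on raw SP).
#' @param welch use the Welch t statistic instead of pooled variance.
#' @param n_perm,seed permutation settings for the ANOVA mode.
#' @return an object of class `group_comparison`: `statistic_name` ("t" or
#'   "F"), `statistic_value`, `p`, `groups`, `n_per_group`,
#'   `percent_decrease`, and `levene` (the recorded homogeneity check, t
#'   mode only).
#' @export
compare_sp_by_genotype <- function(estimates, fragment = "frag_10_18",
                                   bin = "lt25", pa28 = "present",
                                   mode = c("h_carrier_t", "three_group_mc_anova"),
                                   use_standardized = FALSE, welch = FALSE,
                                   n_perm = 10000, seed = NULL) {
  mode <- match.arg(mode)
  sel <- estimates$fragment == fragment & estimates$bin == bin &
    estimates$pa28 == pa28
  d <- estimates[sel, , drop = FALSE]
  if (nrow(d) == 0) {
    stop("no SP estimates in the requested fragment/bin/condition",
         call. = FALSE)
  }
  value_col <- if (use_standardized) "sp_standardized" else "sp"
  if (use_standardized && !"sp_standardized" %in% names(d)) {
    stop("call standardize_within_set() first to use standardized values",
         call. = FALSE)
  }
  carrier <- ifelse(d$genotype %in% c("RH", "HH"), "H_carrier", "RR")
  mh <- mean(d$sp[carrier == "H_carrier"])
  mr <- mean(d$sp[carrier == "RR"])
  pct <- 100 * (1 - mh / mr)

  if (mode == "h_carrier_t") {
    x <- d[[value_col]][carrier == "H_carrier"]
    y <- d[[value_col]][carrier == "RR"]
    if (length(x) < 2 || length(y) < 2) {
      stop("each group needs n >= 2", call. = FALSE)
    }
    lev <- levene_test(d[[value_col]], carrier)
    tt <- student_t(x, y, welch = welch)
    res <- structure(list(statistic_name = "t",
                          statistic_value = tt$statistic,
                          p = tt$p,
                          groups = c("H_carrier", "RR"),
                          n_per_group = c(length(x), length(y)),
                          percent_decrease = pct,
                          levene = lev,
                          welch = welch),
                     class = "group_comparison")
  } else {
    tab <- table(d$genotype)
    if (length(tab) < 2 || any(tab < 2)) {
      stop("each genotype group needs n >= 2", call. = FALSE)
    }
    pa <- perm_anova(d[[value_col]], d$genotype, n_perm = n_perm, seed = seed)
    res <- structure(list(statistic_name = "F",
                          statistic_value = pa$statistic_value,
                          p = pa$p,
                          groups = pa$groups,
                          n_per_group = pa$n_per_group,
                          percent_decrease = pct,
                          permutation = pa),
                     class = "group_comparison")
  }
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison (%s vs %s): %s = %.4g, p = %.4g",
              x$groups[1], paste(x$groups[-1], collapse = "/"),
              x$statistic_name, x$statistic_value, x$p))
  if (!is.null(x$percent_decrease) && !is.na(x$percent_decrease)) {
    cat(sprintf(", percent decrease = %.2f%%", x$percent_decrease))
  }
  cat("\n")
  invisible(x)
}

# Two-sided two-sample t with explicit degenerate handling: zero pooled
# variance gives t = 0, p = 1 for equal means and |t| = Inf, p = 0 otherwise
# (noiseless synthetic data hits this).
student_t <- function(x, y, welch = FALSE) {
  n1 <- length(x)
  n2 <- length(y)
  dm <- mean(x) - mean(y)
  v1 <- stats::var(x)
  v2 <- stats::var(y)
  if (v1 + v2 <= 1e-12 * max(1, dm^2, mean(x)^2)) {
    if (abs(dm) <= 1e-12 * max(1, abs(mean(x)))) {
      return(list(statistic = 0, p = 1, df = n1 + n2 - 2))
    }
    return(list(statistic = sign(dm) * Inf, p = 0, df = n1 + n2 - 2))
  }
  if (welch) {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  t <- dm / se
  list(statistic = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' PA28 effect on SP by Mann-Whitney test
#'
#' Two-sided Mann-Whitney comparison of SP with versus without PA28-alpha/beta;
#' see [mann_whitney()] for the exact-enumeration rule.
#'
#' @param sp_with,sp_without SP values under the two conditions.
#' @param exact_limit enumerate all assignments when the total sample size is
#'   at most this (default 24).
#' @return a `group_comparison` with `statistic_name = "U"`.
#' @export
compare_sp_pa28 <- function(sp_with, sp_without, exact_limit = 24) {
  mw <- mann_whitney(sp_with, sp_without, exact_limit = exact_limit)
  structure(list(statistic_name = "U",
                 statistic_value = mw$u,
                 p = mw$p,
                 groups = c("PA28_present", "PA28_absent"),
                 n_per_group = c(length(sp_with), length(sp_without)),
                 percent_decrease = NULL,
                 method = mw$method),
            class = "group_comparison")
}

#' Mann-Whitney U test with exact small-sample enumeration
#'
#' U is computed for the first sample from midranks. When
#' `n1 + n2 <= exact_limit` the null distribution of U is obtained by
#' enumerating all `choose(n1 + n2, n1)` assignments of the pooled observed
#' values (ties are handled naturally since observed values are permuted);
#' the two-sided p is `min(1, 2 * min(P(U <= u), P(U >= u)))`. Above the
#' limit, the normal approximation with tie correction is used (no continuity
#' correction).
#'
#' @param x,y the two samples.
#' @param exact_limit maximum total n for exact enumeration.
#' @return list with `u` (U of `x`), `p`, `method`.
#' @examples
#' mann_whitney(1:3, 4:6)  # complete separation, p = 2/20
#' @export
mann_whitney <- function(x, y, exact_limit = 24) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  if (n <= exact_limit) {
    idx <- utils::combn(n, n1)
    r1 <- colSums(matrix(r[idx], nrow = n1))
    u_perm <- r1 - n1 * (n1 + 1) / 2
    p_le <- mean(u_perm <= u + 1e-9)
    p_ge <- mean(u_perm >= u - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact_enumeration"
  } else {
    ties <- table(r)
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approximation"
  }
  list(u = u, p = p, method = method)
}

#' Levene's test of homogeneity of variance
#'
#' Classical Levene W: one-way ANOVA F statistic on absolute deviations from
#' the group means, with an F-distribution p-value. Two identical groups give
#' W = 0, p = 1.
#'
#' @param x numeric values.
#' @param g group labels; >= 2 groups with n >= 2 each.
#' @return a `group_comparison` with `statistic_name = "W_levene"`.
#' @export
levene_test <- function(x, g) {
  g <- as.factor(droplevels(as.factor(g)))
  stopifnot(length(x) == length(g))
  tab <- table(g)
  if (nlevels(g) < 2 || any(tab < 2)) {
    stop("Levene's test needs >= 2 groups with n >= 2 each", call. = FALSE)
  }
  z <- abs(x - stats::ave(x, g, FUN = mean))
  w <- f_statistic(z, g)
  n <- length(x)
  k <- nlevels(g)
  p <- if (w == 0) 1 else stats::pf(w, k - 1, n - k, lower.tail = FALSE)
  structure(list(statistic_name = "W_levene", statistic_value = w, p = p,
                 groups = levels(g), n_per_group = as.integer(tab),
                 percent_decrease = NULL),
            class = "group_comparison")
}
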