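#' Fit first-order degradation kinetics to one substrate time-course
#'
#' Least-squares fit of `ln S(t) = ln S0 - K1 * t` over the time points with a
#' positive substrate signal. With multiplicative (lognormal) measurement
#' noise the log-linear fit is the maximum-likelihood estimator and cannot
#' fail to converge. Time points with non-positive signal are dropped from
#' the fit. A non-negative rate is enforced: an upward drift fits as K1 = 0.
#'
#' @param time sampling times in minutes.
#' @param substrate_signal substrate signals at `time`.
#' @return an object of class `kinetics_fit`: list with `k1` (per minute),
#'   `s0` (fitted initial signal), `r_squared`, `k1_se` (standard error of the
#'   slope) and `n_points`.
#' @examples
#' t <- c(0, 30, 60, 120)
#' fit_first_order(t, 100 * exp(-0.01 * t))
#' @export
fit_first_order <- function(time, substrate_signal) {
  stopifnot(length(time) == length(substrate_signal))
  keep <- is.finite(substrate_signal) & substrate_signal > 0 & is.finite(time)
  if (sum(substrate_signal[time > 0] > 0, na.rm = TRUE) == 0) {
    stop("degenerate decay: no positive substrate signal after time 0",
         call. = FALSE)
  }
  if (sum(keep) < 3) {
    stop("insufficient data: need >= 3 time points with positive signal",
         call. = FALSE)
  }
  t <- time[keep]
  y <- log(substrate_signal[keep])
  fit <- stats::lm(y ~ t)
  slope <- unname(stats::coef(fit)[2])
  k1 <- max(0, -slope)
  s0 <- exp(unname(stats::coef(fit)[1]))
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss <= 1e-12) 1 else max(0, min(1, 1 - rss / tss))
  se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  structure(list(k1 = k1, s0 = s0, r_squared = r2, k1_se = unname(se),
                 n_points = sum(keep)),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("First-order kinetics fit: K1 = %.5g /min (SE %.3g), S0 = %.5g, R^2 = %.4f, n = %d\n",
              x$k1, x$k1_se, x$s0, x$r_squared, x$n_points))
  invisible(x)
}

#' Fit kinetics for every degradation set in a digestion table
#'
#' Applies [fit_first_order()] per `set_id` of a digestion table in the
#' standard long format (as produced by [simulate_digestion()] or read by
#' [read_digestion()]).
#'
#' @param digestion digestion data.frame.
#' @return a data.frame with one row per set: `set_id`, `preparation_id`,
#'   `genotype`, `pa28`, `k1`, `s0`, `r_squared`, `k1_se`, `n_points`.
#' @export
fit_kinetics <- function(digestion) {
  check_digestion(digestion)
  sets <- split(digestion, digestion$set_id)
  out <- lapply(sets, function(d) {
    f <- fit_first_order(d$time_min, d$substrate_signal)
    data.frame(set_id = d$set_id[1], preparation_id = d$preparation_id[1],
               genotype = d$genotype[1], pa28 = d$pa28[1],
               k1 = f$k1, s0 = f$s0, r_squared = f$r_squared,
               k1_se = f$k1_se, n_points = f$n_points,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of substrate consumed at a time point
#'
#' `1 - S(t)/S(0)`, clamped to \[0, 1\]. Noise can push a signal above its
#' time-zero value; negative raw fractions are clamped to 0 with a warning.
#'
#' @param time,substrate_signal the time course of one degradation set; must
#'   include time 0 with a positive signal.
#' @param at time(s) at which to evaluate; must be present in `time`.
#' @return fraction(s) consumed in \[0, 1\].
#' @examples
#' fraction_consumed(c(0, 60), c(200, 150), at = 60)  # 0.25
#' @export
fraction_consumed <- function(time, substrate_signal, at) {
  i0 <- which(time == 0)
  if (length(i0) != 1L || !(substrate_signal[i0] > 0)) {
    stop("time course must contain time 0 with a positive substrate signal",
         call. = FALSE)
  }
  idx <- match(at, time)
  if (anyNA(idx)) {
    stop("requested time(s) not present in the time course", call. = FALSE)
  }
  f <- 1 - substrate_signal[idx] / substrate_signal[i0]
  if (any(f < 0)) {
    warning("substrate signal above its time-zero value; fraction clamped to 0")
  }
  pmin(1, pmax(0, f))
}

#' Compare K1 across genotype groups by permutation ANOVA
#'
#' One-way F statistic on fitted rate constants with a permutation p-value
#' (group labels shuffled). See [perm_anova()] for the permutation scheme.
#'
#' @param k1 fitted rate constants.
#' @param genotype group labels (e.g. RR/RH/HH), >= 2 groups with >= 2 fits.
#' @param n_perm number of random permutations when enumeration is not used.
#' @param seed seed for the permutation draw.
#' @param exhaustive_limit enumerate all label arrangements when their number
#'   does not exceed this limit.
#' @return a `perm_anova` result (see [perm_anova()]).
#' @export
compare_k1 <- function(k1, genotype, n_perm = 10000, seed = NULL,
                       exhaustive_limit = 1e5) {
  tab <- table(genotype)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need >= 2 genotype groups with >= 2 fits each", call. = FALSE)
  }
  perm_anova(k1, genotype, n_perm = n_perm, seed = seed,
             exhaustive_limit = exhaustive_limit)
}

#' Permutation one-way ANOVA
#'
#' F statistic of a one-way layout with a permutation p-value. When the
#' number of distinct label arrangements is at most `exhaustive_limit` the
#' null distribution is enumerated exactly and
#' `p = #\{F_perm >= F_obs\} / #arrangements` (the identity arrangement
#' counts, so p > 0). Otherwise `n_perm` random shuffles are drawn and the
#' add-one estimator `p = (1 + #\{F_perm >= F_obs\}) / (n_perm + 1)` is used.
#' Degenerate data (all values equal) give F = 0, p = 1.
#'
#' @param x numeric response values.
#' @param g group labels.
#' @param n_perm number of random permutations.
#' @param seed seed for the random-permutation path.
#' @param exhaustive_limit maximum number of arrangements to enumerate.
#' @return an object of class `perm_anova`: `statistic_name` ("F"),
#'   `statistic_value`, `p`, `method` ("exhaustive"/"monte_carlo"), `n_perm`,
#'   `seed`, `groups`, `n_per_group`.
#' @export
perm_anova <- function(x, g, n_perm = 10000, seed = NULL,
                       exhaustive_limit = 1e5) {
  g <- as.factor(g)
  stopifnot(length(x) == length(g))
  if (nlevels(g) < 2 || any(table(g) < 1)) {
    stop("need >= 2 non-empty groups", call. = FALSE)
  }
  f_obs <- f_statistic(x, g)
  sizes <- as.integer(table(g))
  n_arr <- n_assignments(sizes)
  if (f_obs == 0) {
    # no between-group spread at all: every arrangement does at least as well
    res <- list(p = 1, method = "degenerate", n_perm = NA_integer_)
  } else if (n_arr <= exhaustive_limit) {
    asg <- enumerate_assignments(sizes)
    # map arrangement columns onto the observed value order: arrangements are
    # over sorted-by-group positions; F is label-symmetric so any fixed
    # bijection of positions works
    f_perm <- apply(asg, 2, function(lbl) f_statistic(x, lbl))
    res <- list(p = mean(stat_ge(f_perm, f_obs)), method = "exhaustive",
                n_perm = ncol(asg))
  } else {
    if (!is.null(seed)) set.seed(seed)
    f_perm <- replicate(n_perm, f_statistic(x, sample(g)))
    res <- list(p = (1 + sum(stat_ge(f_perm, f_obs))) / (n_perm + 1),
                method = "monte_carlo", n_perm = as.integer(n_perm))
  }
  structure(list(statistic_name = "F", statistic_value = f_obs, p = res$p,
                 method = res$method, n_perm = res$n_perm,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 groups = levels(g), n_per_group = as.integer(table(g))),
            class = "perm_anova")
}

#' @export
print.perm_anova <- function(x, ...) {
  cat(sprintf("Permutation one-way ANOVA: F = %.4g, p = %.4g (%s, %s permutations)\n",
              x$statistic_value, x$p, x$method,
              ifelse(is.na(x$n_perm), "-", format(x$n_perm))))
  invisible(x)
}

check_digestion <- function(digestion) {
  need <- c("set_id", "preparation_id", "genotype", "pa28", "time_min",
            "substrate_signal", "frag_1_9", "frag_10_18", "frag_19_28")
  miss <- setdiff(need, names(digestion))
  if (length(miss)) {
    stop("digestion table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(digestion)
}
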