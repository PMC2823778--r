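---
title: "Models and methods behind immunoSP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind immunoSP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoSP)
```

immunoSP implements two analysis arms around the LMP2 (PSMB9) codon-60 R60H
polymorphism of the immunoproteasome: quantification of in-vitro epitope
generation from proteasome digestion time courses, and stratified
case-control genetic association. This vignette explains the models, the
tunable parameters and their defaults, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## 1. Digestion arm

### Kinetics model

A digestion experiment incubates the 28-mer myelin basic protein substrate
MBP~102–129~ with one purified 20S immunoproteasome preparation, with or
without the PA28-αβ activator, and quantifies HPLC/ESI-MS signals of the
substrate and of the three tiled fragments (1–9, 10–18 — the HLA-A\*0201
epitope MBP~111–119~ — and 19–28) at several times. Substrate degradation is
modelled as a first-order reaction,

$$S(t) = S_0\, e^{-K_1 t},$$

and `fit_first_order()` estimates $K_1$ (per minute) and $S_0$ by ordinary
least squares on $\ln S(t)$. Under multiplicative (lognormal) measurement
error — the realistic regime for ion-trap quantification, where the
coefficient of variation is roughly scale-free — the log-linear fit is the
maximum-likelihood estimator, has a closed form, and cannot fail to
converge; a nonlinear refinement would change estimates only under additive
error, which we do not assume. Time points with non-positive signal are
dropped from the fit (they carry no information on the log scale) but kept
for consumption calculations. A fitted positive slope is truncated to
$K_1 = 0$, since a rate cannot be negative. Fewer than three positive-signal
points is an error rather than a guess.

### Specific Production

The yield statistic for a fragment at time $t$ is

$$\mathrm{SP}(t) = 1000 \cdot \frac{F(t)}{S(0) - S(t)},$$

fragment signal per unit of consumed substrate signal (the factor 1000 is
cosmetic). The denominator uses the *observed* $S(0) - S(t)$, not the fitted
$S_0(1-e^{-K_1t})$: numerator and denominator then come from the same
detector channel of the same run, so per-set scale (batch) factors cancel
exactly and SP stays model-free. SP is undefined where no substrate has been
consumed; such points (possible under noise at very early times) are dropped
with a warning.

Because product peptides re-enter the proteasome once substrate becomes
scarce, samples are compared only at similar and moderate consumption.
`assign_bin()` partitions consumption into half-open bins
$[0, 0.25)$, $[0.25, 0.35)$, $[0.35, 0.50)$, with $\ge 0.50$ excluded. The
source conventions name only "<25%", "25–35%", "35–50%"; the half-open
boundary (0.25 belongs to the middle bin, 0.50 to the exclusion zone) was
chosen so the bins partition $[0,1]$ totally and deterministically.

### Standardization and group comparisons

Signals from different degradation sets sit on different detector scales.
`standardize_within_set()` z-scores SP within each set × fragment using the
sample (n−1) standard deviation — the convention is declared here because
the procedure it reimplements names none. Zero-variance groups are flagged
and passed through rather than divided by zero. Raw SP is always preserved:
the headline effect size, the percent decrease

$$100\left(1 - \frac{\overline{\mathrm{SP}}_{\text{H-carrier}}}{\overline{\mathrm{SP}}_{\text{RR}}}\right),$$

is computed from unstandardized SP so it reads directly as a yield ratio.
Both raw and standardized comparison paths are exposed
(`use_standardized`), since "standardize, then compare" can be read either
way.

Three tests cover the designed contrasts:

* **H-carrier t** (`compare_sp_by_genotype(..., mode = "h_carrier_t")`):
  pooled-variance two-sided Student t of RH+HH versus RR, preceded by a
  recorded Levene check (classical W on absolute deviations from group
  means). The pooled-variance form matches an analysis pipeline that
  verifies homogeneity first; a Welch variant sits behind `welch = TRUE`.
  Zero-variance (noiseless) groups are handled explicitly: equal means give
  $t = 0, p = 1$; separated means give $|t| = \infty, p = 0$.
* **Three-genotype permutation ANOVA** (`perm_anova()`): one-way F with the
  label-permutation null. All distinct label arrangements are enumerated
  when their count is at most `exhaustive_limit` (default 10^5 — enumeration
  in R beyond that costs more memory/time than it buys; the limit is an
  argument, so exact enumeration remains available for larger designs), and
  the exhaustive p is $\#\{F_\pi \ge F_{obs}\}/\#\Pi$, which includes the
  identity and is therefore never 0. Otherwise `n_perm` random shuffles
  (default 10,000) with the add-one estimator $(1+k)/(B+1)$.
* **PA28 Mann-Whitney** (`compare_sp_pa28()` / `mann_whitney()`): U from
  midranks; for total $n \le 24$ the null distribution is enumerated over
  all $\binom{n}{n_1}$ assignments of the observed values (ties permute
  naturally), and the two-sided p is $\min(1, 2\min(P(U\le u), P(U\ge u)))$.
  Complete separation at $n = 6+6$ gives $p = 2/924 \approx 0.00216$, which
  prints as 0.002 — the group size behind the published "U = 0; p = 0.002"
  is not printed anywhere, and 6+6 is the unique size reproducing that p
  under exact two-sided enumeration; we treat it as an inference, not a
  fact. Above $n = 24$ a tie-corrected normal approximation (no continuity
  correction, matching mainstream statistical packages' asymptotic path) is
  used.

## 2. Association arm

`tabulate_genotypes()` counts genotypes by status within a sex ×
HLA-A\*02-carriage stratum, excluding unknown carriage and missing
genotypes; percentages are reported at 1 decimal. Pairwise contrasts
(`genotype_contrast()`) report:

* **Odds ratio** with the Woolf log-scale CI using $z = 1.959964$ — this
  pairing exactly reproduces the published intervals, whereas exact
  conditional intervals would not. A zero cell triggers a flagged Haldane
  +0.5 on all cells; the published tables never trigger it, but synthetic
  edge cases must be deterministic.
* **Pearson χ²** without continuity correction, and a **Monte Carlo p**:
  tables are sampled from the fixed-margins null with Patefield's algorithm
  (`stats::r2dtable`), and $p = (1+\#\{\chi^2_{sim} \ge
  \chi^2_{obs}\})/(B+1)$. The add-one estimator avoids $p = 0$; seed and
  replicate count are recorded in every stochastic result.

`hwe_test()` is the df = 1 Pearson test against $p^2, 2pq, q^2$ expectations
from the observed allele frequency. `cohort_homogeneity()` compares the
genotype distributions of two case cohorts (a non-significant result
licenses pooling). `onset_age_compare()` is the permutation ANOVA applied to
onset ages, with group means/SDs at 2 decimals.

### Linkage disequilibrium

`em_haplotype_freqs()` estimates haplotype frequencies for two unphased
biallelic loci by EM. Only double heterozygotes are phase-ambiguous; the
E-step splits them between AB|ab and Ab|aB in proportion to current
haplotype-frequency products, the M-step recounts. Iteration starts from
linkage-equilibrium frequencies (the two-locus likelihood along the
phase-ambiguity direction is unimodal in practice; a multistart adds nothing
here) and stops when the log-likelihood gains less than 1e-10; the
log-likelihood is asserted non-decreasing at every step. From the fitted
frequencies, `ld_stats()` computes $D = p_{AB} - p_A p_B$, Lewontin's
$D' = D/D_{max}$ (with $D_{max} = \min(p_A p_b, p_a p_B)$ for $D>0$,
$\min(p_A p_B, p_a p_b)$ for $D<0$, and $D' \equiv 0$ at $D = 0$ to keep the
statistic total), and $r^2 = D^2/(p_A p_a p_B p_b)$. Significance is exposed
as $\chi^2 = 2n r^2$ on the $2n$ chromosomes, df = 1.

Loci genotyped only as carrier/non-carrier (HLA-A\*02, HLA-DRB1\*15) are
coded dominantly — carrier = one copy — which mirrors the typing resolution;
the resulting D′/r² are those of the presence/absence marker, not of the
underlying allele. A locus with no genotype variation (including an
all-carrier column) is reported as undefined LD rather than a number.

### The published-table fixture

`ms_study_subjects()` rebuilds a 2107-row subject table from the published
marginal counts (1262 cases, 845 controls; genotype counts for the female
and male HLA-A\*02-carrier strata). Rows outside the published genotyped
cells carry `lmp2 = NA` and `a02_carrier = "unknown"` so no unpublished
value is ever fabricated; onset ages and DRB1\*15 carriage, published only
as summaries, stay missing. The male stratum's published odds ratios are
internally inconsistent with its own printed counts (the counts give
OR(HH vs RR) = 0.971, not the printed 0.868); the package reproduces the
counts and recomputes statistics from them, and makes no attempt to match
those printed ORs.

## 3. Synthetic-data generators

### Genotype populations

`simulate_population()` draws sex, two carrier loci and the LMP2 genotype
(Hardy-Weinberg proportions of `h_allele_freq`) independently, then assigns
case status from a logistic model: baseline log-odds plus the log odds
ratios of DRB1\*15 carriage, A\*02 carriage, and — only within the female ×
A\*02-carrier stratum — the HH genotype. Defaults are the study's observed
conditions: `h_allele_freq = 0.356` (the control-stratum allele frequency),
`or_a02 = 0.671`, `or_drb115 = 2.525`, `or_hh_in_a02_females = 0.443`.
Onset ages for cases are normal (mean 30.5 y, SD 10 y, floored at 18),
matching the published onset-age summaries in location and spread.

What it does *not* emulate: population stratification, genotyping error,
age/area matching structure, correlation between loci (so generated LD is
null by construction — useful for the LD null tests, silent about real LD),
or sex-specific disease prevalence beyond the modelled interaction. Passing
tests on generated data therefore demonstrate correctness of the estimators
under the stated sampling model, not robustness to real-data artifacts.

### Digestion experiments

`simulate_digestion()` produces one degradation set per preparation × PA28
condition:

$$S(t) = B\,s_0 e^{-K_1 t}, \qquad
  F(t) = B\,y\,(s_0 - s_0 e^{-K_1 t})\,\varepsilon,$$

with $B$ a per-set lognormal detector factor (σ = `batch_scale_sd`),
$\varepsilon$ per-signal lognormal noise (σ = `noise_sd`), $y$ the fragment
yield, and $K_1$ = `k1_base` times `k1_pa28_multiplier` when PA28 is
present. The H-carrier effect multiplies the *epitope* yield of RH/HH
preparations by `h_carrier_yield_ratio`, only when PA28 is present — exactly
the interaction the SP pipeline is designed to detect. Under this model the
noiseless SP equals $1000\,y$ identically, so the recovered percent decrease
equals $100(1 - \text{yield ratio})$ exactly in every bin — the algebraic
anchor for the recovery tests.

Defaults, chosen once as the study conditions: 3 RR / 3 RH / 3 HH
preparations (the real study used 9 lymphoblastoid-cell-line preparations
whose genotype split is unpublished; 3/3/3 is the balanced default),
`k1_base = 0.002`/min with multiplier 2, time points 0–300 min so that both
PA28 conditions populate all three consumption bins, `noise_sd = 0.15`
(≈15% CV, typical of ion-trap quantification), `batch_scale_sd = 0.3`,
`epitope_yield_base = 0.30`, `s0 = 1000` detector units. The number of time
points per curve is likewise unpublished; nine is a realistic digestion
sampling design. Not emulated: fragment-specific ionization beyond a static
yield factor, product re-entry (the ≥50% exclusion exists precisely to make
it negligible), and substrate-level measurement noise (noise enters through
the fragment channel; adding substrate noise would only perturb the bin
edges).

All randomness flows from a single seed through a counter-based substream
scheme (`substream_seed`), so each pipeline stage is independently
reproducible and two runs with the same configuration are identical —
including byte-identical JSON reports.

## 4. Numerical choices and degenerate inputs

* Permutation and Monte Carlo counts of "statistic ≥ observed" use a small
  relative tolerance so the identity permutation always counts.
* `f_statistic` returns 0 for zero total variance and ∞ for zero
  within-group variance with between-group spread; both propagate to exact
  p-values (1 and the minimal attainable p respectively).
* Standard deviations at floating-point noise level (≤ 1e-8 relative) count
  as zero in standardization, so noiseless synthetic data are flagged rather
  than amplified.
* Monte Carlo χ² requires ≥1000 replicates; fewer gives standard errors too
  large to report responsibly.
* EM tolerance is 1e-10 on the log-likelihood with a 1000-iteration cap; the
  boundary (a haplotype frequency of 0) is a legitimate MLE and is reached
  exactly when no double heterozygote supports the missing haplotype.

## 5. Problem sizes used by the test suite

The suite validates estimator calibration at sizes chosen for statistical
resolution: type-I error rates over 500 replicates (binomial 3σ band
±0.029 around 0.05), effect-recovery means over 50–200 generator seeds,
oracle equivalences over 20 random datasets (EM vs a 1e-6-step profile grid,
permutation tests vs full enumeration at n ≤ 10, Monte Carlo χ² vs
fixed-margin enumeration on 2×2 tables). These sizes are the package's own
validation design.

## 6. Known limitations

* The digestion arm analyzes the three tiled fragments only; it does not
  infer cleavage-site maps or full fragment spectra.
* The association arm fits no logistic regression and adjusts for no
  covariates or multiple testing, mirroring the per-contrast reporting it
  reproduces.
* Exact Mann-Whitney enumeration above n ≈ 20 total is memory-hungry
  (choose(24,12) ≈ 2.7M assignments); beyond `exact_limit` the asymptotic
  path takes over.
* Dominant coding of carrier loci caps the information available to the LD
  estimator; with fully typed genotypes the same EM applies unchanged.
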