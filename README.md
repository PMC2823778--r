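# immunoSP

Statistical pipeline for two linked questions about the immunoproteasome
subunit LMP2 (PSMB9) and its codon-60 R→H polymorphism:

1. **In-vitro epitope generation.** Purified 20S immunoproteasomes (± the
   PA28-αβ activator) digest the 28-mer myelin basic protein substrate
   MBP₁₀₂₋₁₂₉ (`PSQGKGRGLSLSRFSWGAEGQRPGFGYG`). Mass-spectrometry signals of
   the substrate and its three tiled fragments — 1–9, 10–18 (the
   HLA-A*0201-restricted epitope MBP₁₁₁₋₁₁₉, `SLSRFSWGA`) and 19–28 — are
   turned into degradation kinetics and an epitope-yield statistic, and
   compared across LMP2 genotypes (RR/RH/HH) and PA28 conditions.
2. **Case-control genetic association.** Stratified tabulation of LMP2
   genotypes in multiple-sclerosis cases and controls, with odds ratios,
   Monte Carlo χ² tests, Hardy-Weinberg checks, linkage disequilibrium and
   onset-age comparisons.

The package is aimed at immunologists and genetic epidemiologists who want
the complete analysis — including the synthetic-data generators used to
validate it — as tested, reusable R functions.

## The statistics at the core

* **First-order kinetics.** The substrate signal follows
  S(t) = S₀·e^(−K₁t); `fit_first_order()` estimates K₁ by least squares on
  ln S(t), the maximum-likelihood fit under multiplicative noise.
* **Specific Production (SP).** For a fragment at digestion time t,
  SP = 1000 · (fragment signal) / (S(0) − S(t)): epitope produced per unit of
  consumed substrate. Samples are compared only at similar consumption
  (bins <25%, 25–35%, 35–50%; ≥50% is excluded to limit product re-entry),
  after within-set z-score standardization when sets must be pooled. Group
  effects are tested with a pooled-variance Student t (H-carriers RH+HH vs
  RR, Levene-checked), a permutation ANOVA across the three genotypes, and
  an exact Mann-Whitney test for the PA28 effect.
* **Association.** OR = (case₁·control₂)/(control₁·case₂) with the Woolf
  log-scale 95% CI exp(ln OR ± 1.959964·√Σ1/nᵢ); Pearson χ² (no continuity
  correction) with Monte Carlo p-values from fixed-margin table sampling;
  Hardy-Weinberg χ² (df = 1); EM haplotype frequencies for unphased locus
  pairs with Lewontin's D′ and r².

## Worked example

```r
library(immunoSP)

# --- association arm: the published female HLA-A*02-carrier stratum ---
subj <- ms_study_subjects()            # subject table rebuilt from the
                                       # published summary counts
gt <- tabulate_genotypes(subj, sex = "female", a02 = "yes")
gt
#> Genotype counts (percentages)
#>         HH        RH         RR
#> case    26 (7.7)  146 (43.3) 165 (49.0)
#> control 32 (15.8) 80 (39.6)  90 (44.6)

genotype_contrast(gt, "HH", "RR", seed = 1)
#> HH vs RR: OR = 0.443 (95% CI 0.249-0.790), chi2 = 7.850 (df 1), p = 0.005 [MC p = 0.0063, 10000 reps]

hwe_test(32, 80, 90)
#> Hardy-Weinberg test: H allele freq = 0.3564, chi2 = 3.7776 (df 1), p = 0.05194

# --- digestion arm: one synthetic experiment, H-carrier yield ratio 0.712 ---
cfg <- digestion_sim_config(h_carrier_yield_ratio = 0.712, seed = 11)
est <- sp_estimates(simulate_digestion(cfg))
compare_sp_by_genotype(est, bin = "lt25", pa28 = "present")
#> Group comparison (H_carrier vs RR): t = -5.175, p = 2.371e-05, percent decrease = 22.74%
```

The genotype contrast says that in this stratum the HH genotype carries
less than half the disease odds of RR (OR 0.443), with an interval clearly
below 1; the Hardy-Weinberg p of 0.052 means the control genotype counts are
compatible with equilibrium. The digestion comparison recovers the injected
H-carrier epitope deficit: a single noisy experiment of 9 preparations gives
a 22.7% decrease (t = −5.2), and because any one simulated experiment is
noisy, averaging independent experiments tightens the estimate — over 20
seeds the mean recovered decrease is 27.50% against the generating value of
28.8%.

`run_association()` and `run_digestion()` execute the entire surface of each
arm in one call and can write JSON/TSV reports; `read_subjects()` /
`read_digestion()` load validated CSV/TSV inputs.

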