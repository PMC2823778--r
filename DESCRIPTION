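Package: immunoSP
Title: Immunoproteasome Epitope Specific Production and Case-Control
    Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for quantifying MHC class I epitope
    generation by purified immunoproteasomes and for stratified case-control
    genetic association. The digestion arm fits first-order degradation
    kinetics to substrate mass-spectrometry time courses, computes the
    Specific Production (SP) statistic of an epitope per unit of consumed
    substrate, standardizes signals within degradation sets, bins samples by
    substrate consumption and compares genotype and PA28-alpha/beta groups
    (pooled-variance t, Levene, exact Mann-Whitney, permutation ANOVA). The
    association arm tabulates stratified genotype counts, computes Woolf
    odds-ratio confidence intervals, Pearson chi-squared tests with Monte
    Carlo p-values on fixed-margin tables, Hardy-Weinberg tests, EM-based
    haplotype frequency estimation with Lewontin's D-prime and r-squared,
    cohort homogeneity checks and permutation tests of onset age.
    Synthetic-data generators with recorded ground truth make every stage
    testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
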