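# petalshift

Multiscale analysis of a blue–orange flower color polymorphism shared by two
closely related species. When two sister species segregate the *same*
discrete color morphs, the variation may have arisen by **convergence**
(independent origins), **introgression** (a single origin transferred by
hybridization), **ancestral polymorphism** (a single origin predating
speciation), or because the **species are not actually monophyletic**.
`petalshift` implements the evidence streams that discriminate these
hypotheses and a rule table that combines them into verdicts, together with
seeded simulators for every input type so the whole pipeline can be
validated against planted ground truth.

The package is aimed at evolutionary biologists working with petal
reflectance spectra, petal RNA-seq, per-gene coding alignments, gene trees,
and occurrence/climate tables for a two-species × two-morph design.

## What it computes

* **Spectra** — distance-based permutational MANOVA (PERMANOVA) on
  curve-to-curve Euclidean distances,
  `d_ij = sqrt(Σ_λ (R_i(λ) − R_j(λ))²)`, partitioning
  `SS_total = SS_between + SS_within` with
  `R² = SS_between / SS_total` and
  `F = (SS_b/(a−1)) / (SS_w/(n−a))`, assessed by free label permutation
  (exact enumeration on small designs); plus inflection-point detection on
  smoothed group mean curves (`compare_partitions()`, `permanova()`,
  `inflection_points()`).
* **Expression** — CPM filtering (CPM > 1 in ≥ 4 samples), TMM
  normalization (doubly trimmed, precision-weighted mean of log ratios), a
  conditional negative-binomial exact test with a method-of-moments common
  dispersion, BH FDR, DEG flags at FDR < 10⁻⁵ and |log₂FC| > 1, a
  Mann–Whitney fallback for low-expression regulators, a DEG direction-bias
  chi-square, and rule-based isotig selection (`de_exact_test()` and
  friends).
* **Variants** — codon-aware color-, species-, and fixed-difference SNP
  calling from in-frame consensus alignments at a 75% allele-frequency
  difference cutoff, with synonymous/nonsynonymous classification under the
  standard genetic code (`color_differentiating_snps()`, ...).
* **Co-expression** — Kendall tau-b correlations among pathway genes with
  exact small-sample p-values (`kendall_tau()`, `correlate_expression()`).
* **Phylogenetics** — monophyly evaluation of labeled tip sets on gene
  trees and a combined tree with bootstrap-support gating at 70%
  (`is_monophyletic()`, `topology_evidence()`).
* **Climate** — occurrence filtering/pixel deduplication, univariate morph
  contrasts, parallel/opposing direction classification, AIC-best logistic
  models of morph, and a Monte Carlo test that randomizes colors within
  species to ask whether same-colored morphs of the two species are more
  climatically divergent than chance (`mc_divergence()`, ...).
* **Hypotheses** — a tri-state rule table turning the evidence profile into
  consistent / inconsistent / indeterminate verdicts per hypothesis
  (`score_hypotheses()`, `build_evidence()`).

## A worked example

```r
library(petalshift)

# spectra: does color morph or species explain more spectral variance?
spectra <- simulate_spectra(n_per_group = 20, color_effect = 30,
                            species_effect = 5, noise_sd = 2, seed = 1)
compare_partitions(spectra, n_permutations = 999, seed = 1)
#>   factor  pseudo_F    R2 p_value mean_between mean_within between_within_ratio
#> 1 morph       353.5 0.819   0.001          319        94.9                3.36
#> 2 species      11.2 0.125   0.002          231       185.7               1.24

# counts: recover 50 planted DEGs at the conservative thresholds
sim <- simulate_counts(seed = 1)           # 1000 genes, 50 planted, phi = 0.1
de  <- de_exact_test(filter_low_expression(sim$counts), sim$meta)
sum(de$deg)
#> [1] 50                                   # all planted, no false flags

# the full pipeline under the ancestral-polymorphism scenario
res <- run_study(simulate_study("ancestral_polymorphism", seed = 1), seed = 1)
res$assessment[c("hypothesis", "verdict")]
#>   hypothesis             verdict
#>   convergence            inconsistent
#>   introgression          inconsistent
#>   ancestral_polymorphism consistent
#>   non_monophyly          inconsistent
```

The morph grouping explains ~0.82 of squared spectral distance versus ~0.13
for species (a ~6.5× ratio), the exact test flags exactly the planted DEG
set, and the evidence profile singles out ancestral polymorphism — the
expected outcome for that scenario.

A thin command-line driver is included:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "petalshift.R", package = "petalshift"))')" \
  run --hypothesis ancestral_polymorphism --seed 1
```

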