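---
title: "Methods: deciding how a shared flower color polymorphism arose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deciding how a shared flower color polymorphism arose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petalshift)
```

# The question

Two closely related species each segregate the same discrete blue and
orange petal morphs. Four evolutionary routes can produce such a shared
polymorphism: independent origins in each species (convergence), a single
origin moved across the species boundary by hybridization (introgression),
a single origin in the common ancestor that persisted through speciation
(ancestral polymorphism), or an apparent sharing that is really an artifact
of the species not being reciprocally monophyletic. These hypotheses
make different predictions about petal spectra, pigment-pathway gene
expression, coding-sequence variation, gene-tree topology, interspecific
fertility, and climate niches. `petalshift` implements each evidence
stream and a rule table that converts the joint evidence into per-hypothesis
verdicts, plus seeded generators that plant known structure in every input
type so the pipeline can be validated end to end.

Everything below describes what the package computes; no empirical claim is
made that the test suite or `scripts/acceptance.R` does not itself compute.

# Spectral variance partitioning

Petal reflectance curves (percent reflectance on a common 300–700 nm, 1 nm
grid; curves on other grids are linearly interpolated and clipped at 0) are
compared by the Euclidean distance over wavelengths. The one-factor
permutational MANOVA partitions the total squared distance

$$SS_T = \frac{1}{n}\sum_{i<j} d_{ij}^2,\qquad
  SS_W = \sum_g \frac{1}{n_g}\sum_{i<j\in g} d_{ij}^2,\qquad
  SS_B = SS_T - SS_W,$$

with $R^2 = SS_B/SS_T$ and pseudo-$F = (SS_B/(a-1))/(SS_W/(n-a))$.
Significance comes from free permutation of the group labels. When the
number of distinct label arrangements is at most 10,000 the null is
enumerated exactly and $p = \#\{F \ge F_{obs}\}/N$ (counting the identity);
otherwise $p = (\#\{F_{perm}\ge F_{obs}\}+1)/(B+1)$ with $B = 9999$ by
default, which keeps $p > 0$ and matches standard practice. A design is run
twice — grouped by morph and grouped by species — and both $R^2$ values,
their ratio, and the between/within mean-distance ratio per factor are
reported, because "how much more does color matter than species" can be
read off either statistic and the two are not interchangeable.

Inflection points of a morph's mean curve are found on a moving-average
smooth (default window 11 grid steps; the window is a tunable because the
appropriate smoothing is instrument-dependent) as sign changes of the
discrete second difference, ranked by local slope so the primary landmarks
come first. Exact zeros of the second difference — which arise on
symmetric analytic curves — are skipped over rather than treated as
crossings.

Ordination (NMDS) is deliberately excluded: it is presentation, not
inference; the distance matrix itself is exportable.

# Differential expression

Counts are filtered to genes with CPM strictly above 1 in at least 4
samples, then normalized by TMM: the reference sample is the one whose
upper-quartile CPM is closest to the mean upper quartile; per sample, the
gene-wise log2 abundance ratios to the reference (M) and average log2
abundances (A) over genes positive in both are doubly trimmed (30% of M and
5% of A from each tail) and combined by a precision-weighted mean; factors
are rescaled to geometric mean 1. The implementation follows the standard
construction and is cross-checked against an independent reference
implementation in the test suite. Library sizes default to column sums but
may be overridden, which is also how the worked doubling example (factors
$2^{\mp 1/2}$ for an elementwise-doubled sample at fixed library sizes) is
expressed.

Testing uses a conditional negative-binomial exact test with a single
common dispersion $\phi$, estimated by the method of moments on counts
scaled to a common effective library size: per gene and group with scaled
mean above 5, $\hat\phi = \max(0, (s^2-m)/m^2)$, averaged. This is a
deliberate simplification relative to tagwise-shrinkage machinery: with a
single generating dispersion (the regime the simulators produce) a common
estimate is adequate, and it keeps the exact test self-contained. Group
sums of the scaled pseudo-counts are compared conditionally on their total:
with group sizes $n_1, n_2$ the sums are NB with sizes $n_i/\phi$ and means
$n_i\hat\mu$, and the two-sided p-value adds the probabilities of all
splits at most as likely as the observed one. At $\phi = 0$ this collapses
exactly to binomial enumeration, which the tests verify for every total up
to 30.

Log2 fold changes are computed from group mean CPM with a prior count of
0.5 so that orange-specific paralogues — genes essentially silent in blue
petals — get large but finite values. DEGs require FDR < $10^{-5}$
(Benjamini–Hochberg) *and* |log2FC| > 1, both directions. A two-sided
Mann–Whitney test is provided as a separate fallback for low-expression
regulatory genes and is never mixed into the FDR pool, since its p-values
come from a different null machinery. The DEG direction-bias test is a
1-df goodness-of-fit chi-square of the O>B / B>O counts against 50:50; note
that for a few hundred DEGs split roughly 1.19:1 this statistic is of order
1–10, so headline chi-square values in the thousands cannot arise from
those direction counts — the operation implements the stated comparison and
reports the count ratio alongside.

Isotig selection applies the four sample-level criteria in order —
ambiguity fraction < 20%, mapped reads > 100, longest CDS, highest
expression (rank-based, as no threshold is defined for "higher expression")
— and then picks the isotig present in the most samples, breaking ties
lexicographically (deterministic, flagged).

# Coding-sequence variants

Each gene's alignment holds one consensus sequence per sample over
`A,C,G,T,N,-`; any IUPAC ambiguity is treated as `N`, and frequencies are
computed over unambiguous calls only, with columns uncallable when any
group has fewer than two such calls. A site is color-differentiating when
the absolute alternate-allele frequency difference between morphs is at
least 0.75 (inclusive, making the boundary testable; the 0.70 variant used
in some displays is reachable via the `cutoff` argument), and
species-differentiating under the same rule with species grouping.
Effects are classified by substituting the alternate base into the majority
codon and translating with the standard genetic code; codons containing a
gap or `N` in the majority background are skipped as uncallable.
Completely fixed color differences additionally require every unambiguous
blue sample (both species) to carry one base and every orange sample the
other. Coordinates are 1-based alignment columns throughout.

# Co-expression

Kendall's tau-b (tie-corrected) measures monotone association between
pathway genes within each species on normalized expression. For $n \le 8$
without ties the two-sided p-value is exact, from the inversion-count
distribution of permutations; otherwise the tie-corrected normal
approximation is used. Significance defaults to raw $p \le 0.001$, the
reading under which a reported $p = 0.0062$ is non-significant and
$p = 2.9\times 10^{-4}$ significant; dividing $\alpha$ by the number of
pairs is available via `divide_alpha` because the intended multiple-testing
family (all pairs versus a chosen subset) is genuinely ambiguous. Every
pair is always reported, significant or not.

# Trees and monophyly

Trees arrive as Newick with bootstrap supports as internal node labels;
inference itself (ML search, bootstrapping) is upstream and out of scope.
Monophyly of a labeled tip set uses the unrooted bipartition criterion by
default (some bipartition separates exactly the query from the rest;
a polytomy whose descendants equal the query counts), or the rooted-clade
criterion when an outgroup is supplied; the two agree whenever the outgroup
is disjoint from the query, and results are invariant to tip order and to
rerooting outside the queried clade. A clade is "supported" when its node's
bootstrap is at least 70, the conventional reporting threshold. The
evidence table asks, per gene tree, whether the orange samples of both
species form a clade and whether orange is monophyletic within each
species; and, on the combined tree, whether the species are reciprocally
monophyletic and the morphs monophyletic within species.

# Climate niches

Occurrences are filtered (complete climate records only) and deduplicated
per species × morph within 30 arc-second pixels, the resolution of the
highest-resolution BIOCLIM grids. Univariate contrasts (the two
within-species color contrasts and the two between-species same-color
contrasts) default to two-sided Mann–Whitney with Bonferroni correction
across the variables in each family; a Welch option exists because the
underlying test choice is a documented package decision rather than a
fidelity claim. Variables significant for the color contrast in both
species are classified parallel or opposing by the sign of (mean orange −
mean blue) per species.

The divergence test asks, per variable and color $c$, whether
$D_c = |\bar v_{A,c} - \bar v_{B,c}|$ is larger than expected when color
labels are randomized within each species independently (preserving
per-species color counts). The plain difference of means is the minimal
reading of "climatic difference"; a pooled-SD-standardized variant is a
flag. With few records the within-species arrangements are enumerated
exactly ($p = \#\{D_{null} \ge D_{obs}\}/N$); otherwise 9999 Monte Carlo
permutations with the +1/+1 convention. No correction is applied across
the 19 variables by default, matching per-variable reporting; a Bonferroni
flag exists. P-values are invariant to shifting a variable and unchanged
by scaling (the statistic scales).

Logistic models of morph use z-scored predictors, exhaustive best-subset
search up to `k_max = 5` variables by AIC (falling back to bidirectional
stepwise above a fit budget), predictors ranked by absolute standardized
coefficient, and explicit detection of complete separation instead of a
diverged fit. One calibration caveat is worth stating: best-subset
selection over $k$ null predictors beats the intercept-only model by more
than 2 AIC with probability $1-(1-P[\chi^2_1>4])^k$ approximately, which is
substantial for $k$ near 19 — so "the intercept survives within 2 AIC" is
only a useful null expectation for small candidate sets, and that is how
the package tests it.

# The rule table

Six tri-state evidence fields (true / false / unknown) feed four rule rows:

| hypothesis | requires |
|---|---|
| convergence | no cross-species orange clade at color genes; no shared color NS SNP set |
| introgression | cross-species orange clade; interspecific fertility |
| ancestral polymorphism | cross-species orange clade; species monophyly in the combined tree |
| non-monophyly | cross-species orange clade at all loci, i.e. combined tree lacks species monophyly |

A contradicted requirement makes a hypothesis inconsistent; an unknown
requirement (absent a contradiction) makes it indeterminate; unknowns never
produce "consistent". Verdicts are qualitative by design: the underlying
argument is one of elimination, and no generative model is available to
score likelihoods. Note the rows are not mutually exclusive — evidence
with a cross-species orange clade, species monophyly *and* fertility is
consistent with both introgression and ancestral polymorphism; in the
motivating system it is the observed *absence* of interspecific fertility
that eliminates introgression.

# The synthetic data and what passing tests mean

The generators are pure functions of their parameters including a single
integer seed (the caller's RNG state is saved and restored), and every
planted structure is returned in a truth table that downstream recovery
tests consume. Defaults encode the study conditions the pipeline targets:

* **Spectra**: 20 samples per species × morph cell; fixed Gaussian bump
  templates (the orange template has bumps at 350 and 420 nm, giving the
  double UV peak; blue a single visible bump), morph amplitude 30, species
  amplitude 5, noise SD 2 reflectance units. Positions are config, not fits
  to real petals — only the variance structure matters downstream.
* **Counts**: 1000 genes, 10 samples per morph, baseline means
  $2^{U(3,8)}$, NB dispersion 0.1, 5% planted DEGs at |log2FC| = 3 (signs
  alternating), two of them orange-specific paralogues with blue-petal mean
  0.05 counts, library size factors in (0.7, 1.4).
* **Alignments**: 150 codons; 13 shared color nonsynonymous sites (the
  focal-gene count in the motivating system), optional synonymous and
  species sites, all at disjoint codons, never creating stop codons;
  ambiguity replaces bases with `N` uniformly. Under the convergence
  scenario each species instead receives its own private color sites.
* **Trees**: topology templates per hypothesis (species-monophyletic with
  nested morph clades, versus a cross-species orange clade), branch lengths
  uniform, supports set to 100.
* **Occurrences**: independent normals per cell (a correlation structure is
  deliberately not defaulted — the divergence test is univariate); the
  standard scenario shifts 15 of 19 variables by 3 SD in one species'
  orange morph.

These simulations validate the *machinery*: that the statistics are
computed correctly, the planted structure is recovered at the stated
thresholds, and the verdict logic is sound. They do not establish anything
about real petals — real spectra have correlated wavelengths, real counts
have gene-specific dispersions and expression-dependent trends, real
alignments have indels and linked sites, and real occurrence data are
spatially autocorrelated. Passing tests therefore mean the pipeline does
what it claims on data whose answer is known, which is the precondition
for, not a substitute for, biological inference.

# Numerical choices and problem sizes

Exact enumerations replace Monte Carlo whenever the arrangement count is at
most 10,000 (PERMANOVA and the climate test) or $n \le 8$ without ties
(Kendall). Observed-statistic comparisons use a $10^{-12}$-scale tolerance
so ties with the observed value count as at least as extreme. Degenerate
inputs are flagged rather than erroring where a flag is meaningful: an
all-zero distance matrix, constant vectors in correlations, zero DEGs in
the direction test, complete separation in the logistic fit, a query
covering all tips.

The test suite and acceptance script run on scaled instances chosen as the
smallest sizes at which the properties are informative: 50 random
PERMANOVA instances at $n \le 8$ against exhaustive enumeration, DEG
recovery over 10–20 seeds of the 1000-gene scenario, 500 null datasets for
the climate test's type-I error, and full 3^6 enumeration of the rule
table. The end-to-end scenario uses the default study sizes above.

# Known limitations

Single common NB dispersion (no tagwise or trended estimation); two-group
designs only; consensus-base variant model (no diploid genotypes or
read-level calling); no branch-length or dating inference; no spatial
autocorrelation handling in the climate tests; verdicts are qualitative
consistency statements, not posterior probabilities.
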