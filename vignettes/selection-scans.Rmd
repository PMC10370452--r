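---
title: "Selection scans and association testing with sweepscan: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection scans and association testing with sweepscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sweepscan)
```

This vignette is the package's own account of the statistical methods it
implements, the conventions it adopts where the literature leaves choices
open, and what its simulation-based validation does and does not
demonstrate.

## The study design

`sweepscan` targets the classic three-population scan: a focal population
A in which recent positive selection is suspected, a closely related
sister population B, and an outgroup C. The data are phased diploid
haplotypes at biallelic SNVs, polarized so allele 1 is the derived state.
Three complementary signals are computed per site and merged:

1. allele-frequency differentiation concentrated on the focal branch
   (Weir–Cockerham F~ST~ → PBS),
2. extended haplotype homozygosity around the focal allele (nSL within A,
   XP-nSL between A and B),
3. a composite empirical-p test that combines PBS with |normalized nSL|
   at intermediate derived allele frequencies via the harmonic mean
   p-value.

A candidate variant is then tested for phenotype association with
additive/dominant linear models adjusted for sex and genotype principal
components.

## Per-site F~ST~ and PBS

`wc_fst()` computes the Weir–Cockerham (1984) variance components per
site from each population's genotype-complete diploid count, allele
frequency and heterozygote frequency: `a` (among populations), `b` (among
individuals within populations), `c` (within individuals), and the
per-site ratio `fst = a / (a + b + c)`. Conventions the estimator's
definition does not fix:

* **Negative estimates** are clamped to 0 and values above 1 to 1. The
  unbiased estimator fluctuates below zero when true differentiation is
  small; a negative branch length has no meaning in PBS.
* **Pairs monomorphic across both populations** give `a = b = c = 0`.
  These take `fst = 0` (the no-differentiation limit) rather than
  "undefined": PBS at focal-specific variants — precisely the variants a
  scan cares about — needs the sister–outgroup pair, which is usually
  monomorphic there.
* **F~ST~ = 1** is capped at `1 - 1e-12` inside the branch transform
  `T = -ln(1 - fst)` so branch lengths stay finite.
* Sites with fewer than two genotype-complete diploids in either
  population are undefined and excluded from PBS with a logged count.

`pbs()` then returns `(T_AB + T_AC - T_BC) / 2`. Summaries across sites
use the ratio-of-sums `sum(a) / sum(a+b+c)` (`wc_fst_global()`); the
unweighted mean of per-site ratios is biased downward (about 0.082 for a
true 0.1 at n = 100) because each per-site ratio carries its own noisy
denominator. Per-site values, as used by PBS, are unaffected.

Calibration: under the Balding–Nichols model (`balding_nichols()`), where
each population's allele frequency is Beta-distributed around an
ancestral frequency with divergence parameter F, the ratio-of-sums
estimate over 5,000 sites recovers F = 0.1 to within 0.01.

## Haplotype shared-length statistics

For a pair of haplotypes, SL at a focal site is the number of sites in
the maximal contiguous run of identical alleles containing the focal
site. Conventions adopted (and applied consistently in the brute-force
oracles used by the test suite):

* The focal site itself is counted, so allele-conditioned pairs always
  score at least 1.
* Runs truncate silently at the matrix edge; there is no edge exclusion
  zone. Edge effects shorten SL symmetrically in numerator and
  denominator classes and are reported per site so users can mask.
* A site where either haplotype is missing neither breaks nor shortens a
  run (it is treated as a match and counted); configurable pair
  exclusion was considered and rejected as it discards whole sites for a
  single missing sample.
* In XP-nSL, where all within-population pairs are used, a pair that
  differs at the focal site has no identity run containing it and scores
  SL = 0.

`nsl_scan()` reports `ln(SL_anc / SL_der)` for sites with MAF > 0.05 and
at least two carriers of each allele; `xpnsl_scan()` reports
`ln(SL_pop1 / SL_pop2)` over all pairs. Normalization
(`normalize_scores()`) standardizes to zero mean and unit *population*
standard deviation within DAF bins (nSL) or globally (XP-nSL). The bin
width defaults to 2% — the genome-scale convention — but for region-scale
data of a few hundred sites the package's own analyses use 10% bins so
each bin holds enough scores to estimate its mean and spread; a bin with
fewer than two defined scores, or zero variance, leaves its scores
undefined rather than fabricating a z-score.

Whether nSL normalization should use DAF or MAF bins is not settled in
the scan literature; DAF bins are used here because the composite test is
defined on the derived-allele spectrum.

## The composite test

`composite_test()` implements, in order:

1. restriction to the closed intermediate-frequency window
   15% ≤ DAF ≤ 50% (both bounds inclusive, as printed);
2. 4%-wide DAF bins anchored at 0.15 (0.15–0.19, …, with a truncated
   final bin 0.47–0.50 kept as its own bin, closed at 0.50);
3. within-bin upper-tail empirical p-values
   `p_i = #{s_j >= s_i} / N_bin` for PBS and for |normalized nSL| —
   ties share the larger p (conservative), a singleton bin gives p = 1;
4. removal of any site where either p exceeds 0.5: the harmonic mean
   p-value is unreliable above 0.5, and since the merged value needs both
   components the whole site is dropped, not one statistic;
5. `HMP = (w1 + w2) / (w1/p1 + w2/p2)` with equal weights by default;
6. flagging of the smallest `ceiling(0.05 N)` merged values, with ties
   at the cutoff all included (and warned about).

No asymptotically-exact HMP correction is applied: the test is used with
an empirical top-fraction rule, not a nominal size, so the raw harmonic
mean is the right object. Double standardization of nSL (frequency-bin
normalization followed by a second standardization inside the 4% DAF
bins) was considered; the single standardization is the default because
the empirical p-values are rank-based within DAF bins anyway, which makes
a second affine standardization inside those bins nearly inert.

**The background panel.** Empirical p-values only mean "extreme relative
to the genome" when the reference is predominantly neutral. A single
swept region ranked against itself competes with its own hitchhikers, and
the empirical tail saturates. `composite_scan(background = )` therefore
pools the query region with additional regions — in validation, a panel
of 8 neutral simulated regions (`neutral_panel()`) — before binning and
ranking. This is the desk-scale analogue of a genome-wide empirical
distribution, and it is how the package's power study is run.

## The simulators

`wright_fisher_sim()` is a discrete-generation forward simulator chosen
over coalescent machinery because its update rules are fully explicit and
it exercises sweeps directly. Design of the default study conditions:

* **Demography.** One ancestral deme of N = 500 diploids evolves for 80
  burn-in generations; the outgroup splits 120 generations before
  present, the sister 60; no migration. Sample sizes default to
  46 / 112 / 48 diploids (focal / sister / outgroup), the cohort sizes of
  the motivating three-population design.
* **Region.** 500 sites ("segregating-site grid") with per-adjacent-site
  crossover probability 2e-4 — roughly 20 kb SNV spacing at 1 cM/Mb —
  and site-wise mutation probability 2e-5 with re-mutation allowed
  (finite sites keep the grid aligned across populations). The region
  size is chosen so the intermediate-DAF window retains enough sites for
  4% bins to be meaningfully populated.
* **Founding variation** draws each site's derived frequency from a
  1/x-shaped spectrum on [0.05, 0.95], the shape of a neutral
  site-frequency spectrum restricted to common variation.
* **The sweep.** Fitness is (1, 1 + hs, 1 + 2s) by focal-site genotype;
  the default h = 1 makes selection genic (additive in fitness). The
  derived allele arises at the sister split on a single donor haplotype
  at frequency 0.02 — a young, single-origin allele, which is the regime
  in which haplotype-length statistics have power. Replicates are
  conditioned by rejection (logged attempt counts) on the sampled focal
  DAF landing in a requested window; there is no trajectory conditioning.

`balding_nichols()` provides the analytic-expectation substrate for F~ST~
calibration, and `simulate_phenotypes()` generates
`log y = beta_g * dosage + beta_sex * sex + e`, returning the raw
`exp()` phenotype so the pipeline's log transform is exercised. Phenotype
defaults emulate a log-scale exhaled-NO-like trait: additive effect 0.20
per minor allele, sex difference 0.37, residual sd 0.6, minor allele
frequency 9%, cohort n = 290 in the recovery study — values at which the
additive model's confidence interval has roughly the width seen in
field-scale studies of this kind.

## Association stage

Genotypes are coded for the minor allele (additive 0/1/2, dominant 0/1);
missing genotypes, phenotypes or covariates drop the sample
(complete-case). PCs come from an SVD of the LD-pruned (`r² > 0.8`,
greedy 50-site windows advanced by 5), frequency-standardized dosage
matrix with mean imputation of missing dosages and a sign convention
(largest-magnitude loading positive) for reproducibility. The confidence
interval uses the t quantile at the model's residual degrees of freedom
rather than a fixed 1.96; at n = 290 the difference is negligible but the
convention is stated. The reported R² is the full-model R², labeled as
such. Relatedness exclusion is an input list; kinship estimation is out
of scope.

Validation (reproduced by `scripts/acceptance.R` and the test suite):
over 200 replicates at n = 290 with true additive effect 0.20, the mean
estimate is within 3 Monte-Carlo standard errors of truth and 95% CI
coverage is 93–95%; under the null the type-I error at 0.05 is 4–5% over
2,000 replicates.

## Numerical and degenerate-input conventions

* VCF positions are 1-based and stay 1-based; internal site indices are
  0-based only at the I/O boundary.
* Missingness QC removes individuals before sites (high-missing samples
  would otherwise inflate site missingness). The two-stage single-pass
  filter is not guaranteed idempotent for adversarial missingness
  patterns concentrated at the thresholds; on typical data a second pass
  is a no-op.
* DAF bin edges are computed with a 1e-9 guard so values like 0.19 land
  in the bin their decimal representation names.
* Frequencies use called-allele denominators; Weir–Cockerham components
  use genotype-complete diploids only.
* Degenerate inputs fail loudly: empty regions, all samples removed,
  monomorphic sites offered for association, rank-deficient designs
  (named collinear columns), non-positive bin widths.

## What the validation does and does not show

The simulations validate *internal* correctness and calibration: exact
agreement with brute-force oracles, recovery of known generative
parameters, rank-uniformity of empirical p-values, and sweep-detection
power under the simulator's own model (detection rate about 0.6–0.8 for
a conditioned additive sweep at s = 0.05, N = 500, with neutral sites
flagged at ~5%). They do not emulate real-data complications:
demographic misspecification (bottlenecks, migration, admixture),
background selection, phasing and polarization error, genotyping batch
effects, or cryptic relatedness beyond an exclusion list. Desk-scale
problem sizes (hundreds of sites, N = 500, tens of generations of
selection) are orders of magnitude below genome scale; empirical
thresholds from such regions have coarse resolution, which is why the
composite analyses pool a neutral background panel and why headline
genome-scale quantities (e.g. a 1% XP-nSL threshold from millions of
SNVs) are not reproduced here.
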