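---
title: "Methods: pair-based analysis of low-coverage ancient genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pair-based analysis of low-coverage ancient genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleopair)
```

## The setting

paleopair targets a recurring situation in archaeogenetics: one or two
shotgun-sequenced ancient individuals at low coverage (well below 1x up to a
few x), analysed against a modern SNP reference panel with per-population
diploid genotypes. At such coverage diploid genotype calls are unreliable, so
every statistic here works from *pseudohaploid* data -- at each panel SNP one
sequencing read is drawn at random and its allele is taken as a haploid call.
Transition SNPs (C/T and G/A) can carry post-mortem cytosine-deamination
artefacts and can be masked throughout.

## Pseudo-twin kinship test

With only two individuals from an otherwise unsampled population, the usual
kinship estimators fail for want of a baseline: no allele frequencies and no
known-unrelated pairs exist for the population. The package instead samples
*two distinct reads* per individual at every site with at least two reads,
producing two pseudohaploid genomes from one diploid individual. These
"pseudo-twins" behave exactly like identical twins in a pairwise comparison:
their expected mismatch rate is the probability that two random gene copies
of one individual differ, i.e. half the expected mismatch of two unrelated
individuals from the same population.

For kinship coefficient $\theta$ (unrelated 0, first degree 1/4, identical
genomes 1/2), the expected mismatch between pseudohaploids of two
individuals is $2\bar{pq}(1-\theta)$ while the within-individual pseudo-twin
mismatch is $\bar{pq}$, so

$$ R \;=\; \frac{d_{\text{between}}}{\tfrac12 (d_{\text{within},1} +
d_{\text{within},2})} \;\xrightarrow{\;E\;}\; 2(1-\theta) , $$

giving 2.0 / 1.5 / 1.0 for unrelated, first-degree and identical pairs.
`kinship_test()` classifies by the nearest expected ratio, gated at 3
jackknife SEs; anything outside the gate is `indeterminate`. The gate is
deliberately conservative: at low overlap it prefers "indeterminate" to a
false relatedness claim.

Two caveats are intentional. First, sequencing error inflates the within-
and between-distances additively and no correction is applied (none is
standard for this statistic); the ratio is therefore attracted very slightly
towards 1 at realistic error rates (about 0.01 at error rate $10^{-3}$ and
heterozygosity 0.2 -- well inside one jackknife SE at 20k sites). The
analytic value $2(1-\theta)$ is exact only in the noiseless model, which is
why the recovery property tests run the generator at its default error rate
of zero while the single worked-example check keeps error $10^{-3}$ and its
wider +/-0.1 band. Second, the single pseudohaploid genomes used for the
between-distance are drawn independently of the twin pair; the expectation
is identical either way, and independent draws keep the numerator and
denominator uncorrelated at a site.

## Conditional nucleotide diversity

`conditional_nucleotide_diversity()` is the pairwise mismatch of the two
pseudohaploid genomes restricted to *transversions polymorphic in the
ascertainment panel* (by default the whole genotype panel, i.e. the array as
a whole; a named population subset is configurable). Conditioning on a fixed
ascertained site set makes the number comparable across samples of different
coverage; excluding transitions removes deamination artefacts. It decreases
with drift (smaller populations are less diverse) -- the property the
package tests -- but its absolute level depends on the ascertainment scheme,
so values are only comparable within one panel.

## Weighted block jackknife

Nearby SNPs are correlated through linkage; naive per-site resampling
understates every standard error. All statistics therefore report SEs from
a weighted block jackknife: the (chromosome, position)-sorted site map is
cut into contiguous blocks (default 50, chromosome boundaries always start
a new block; block counts per chromosome are allocated proportionally by
largest remainder), each statistic is written as a ratio of per-block sums,
and the Busing-style weighted delete-one-block variance

$$ \widehat{\mathrm{Var}}(\hat\theta) = \frac1B \sum_b
\frac{(\tau_b - \theta_J)^2}{h_b - 1}, \qquad
\tau_b = h_b\hat\theta - (h_b-1)\hat\theta_{-b}, \quad h_b = n/m_b $$

is applied with SNP-count weights $m_b$. With singleton equal blocks this
reduces exactly to $s^2/n$ for a mean (tested to 1e-12). Statistics are
ratios of sums over all usable sites, not means of per-block ratios,
matching the standard f-statistic estimators.

## f-statistics

`f3_outgroup(A, B; O)` is the mean of $(p_A-p_O)(p_B-p_O)$: shared drift of
A and B relative to outgroup O, used to rank candidate populations by
affinity to the test individuals (`rank_affinity()`, ties broken
lexicographically). No heterozygosity normalisation is applied: with a fixed
outgroup the ranking is invariant to it, and the unnormalised estimator is
safe for single-read pseudohaploid "populations" where within-population
heterozygosity is not estimable. `d_statistic(W, X; Y, Z)` is the usual
normalised ABBA-BABA ratio; its jackknife Z-score calibration (about 5% of
null simulations beyond |Z| = 2) is part of the test suite. Each statistic
uses the sites with data in all of its populations (complete cases per
statistic), recorded in `n_sites`.

## Admixture proportions (qpAdm-style)

The target T is modelled as a mixture of $k$ sources relative to $m$ right
populations. With pivot $R_1$ (first listed; the estimate is invariant in
expectation, and tested for invariance, to reordering the rest):

$$ y_j = f_4(T, R_1;\, R_{j+1}, R_1), \qquad
X_{ji} = f_4(S_i, R_1;\, R_{j+1}, R_1), \qquad j = 1..m-1 . $$

Because $f_4$ is linear in its first slot, $p_T = \sum_i w_i\, p_{S_i}$
implies $y = Xw$ exactly. `fit_qpadm()` minimises
$(y-Xw)^\top \Omega^{-1} (y-Xw)$ subject to $\sum w_i = 1$:
an equality-constrained OLS solution provides residuals, their weighted
block-jackknife covariance gives $\Omega$, and one GLS refinement gives the
reported weights. The model p-value is the upper $\chi^2_{m-k}$ tail of the
minimised form ($m-1$ equations, $k-1$ free parameters). Weight SEs come
from a block jackknife of the *entire* fitting functional -- each
leave-one-block-out refit re-estimates $\Omega$ too; reusing the full-data
$\Omega$ was measured to understate the SEs noticeably, a known optimism of
feasible GLS. A singular $\Omega$ falls back to a 1e-9 ridge on the
diagonal (this happens by construction when the target is an exact source
copy, where residuals are identically zero and the p-value is 1).

Feasibility follows the field's reporting convention: a model is infeasible
as soon as any *point estimate* is negative, even when its interval covers
zero. `nested_model_search()` fits every non-empty source subset and orders
models by parsimony (ascending source count), then fit (descending
p-value).

With only 50 blocks and $m-1=5$ equations, $\Omega$ carries appreciable
Wishart noise, so the GLS refinement has slightly more sampling variance
than constrained OLS and the chi-square p-value is mildly anticonservative
(rejection near the upper end of the accepted [2%, 10%] band at nominal
5% in the package's own calibration runs). The full-functional jackknife
keeps the weight SEs honest under this noise -- in 200-replicate
calibration the reported SE matched the empirical SD of the estimator to
within 1%. The covariance construction is this package's definition,
validated by these recovery and calibration properties rather than by
real-data tables.

## Sex inference and phenotype screening

`infer_sex()` uses the Y-read fraction $R_y = n_Y/(n_X+n_Y)$ with a normal
binomial interval: XX when the whole interval lies below 0.016, XY when it
lies above 0.075 (the published convention; both thresholds configurable),
indeterminate otherwise or below `min_reads` (default 100).

`screen_variants()` counts quality-passing reads per configured variant:
heterozygous as soon as both alleles are observed; homozygous only from
`min_hom = 3` unopposed reads (a single unopposed read stays uncalled --
a deliberate guard against error and residual damage, since the evidence
threshold for *excluding* an allele is weaker than for observing one).
Dominant traits (e.g. the five lactase-persistence variants shipped as the
default table, hg19 coordinates upstream of LCT in MCM6 introns) are called
positive from any called derived allele; recessive traits only from a
homozygous-derived call.

## The synthetic-data generator

`simulate_dataset()` produces the world every statistic assumes:

* **Sites**: `n_snps` SNPs spread over 22 chromosomes, allele pairs uniform
  over the six unordered nucleotide pairs (so ~1/3 transitions), genetic
  positions at 1e-8 morgans/bp.
* **Frequencies**: ancestral $p_0 \sim U(0.05, 0.95)$ per site (an
  ascertained-panel stand-in: common variants, few rare alleles); each
  population drifts by Balding-Nichols ($\mathrm{Beta}$ with mean $p$ and
  variance $F p(1-p)$) from the ancestral pool, a named parent population,
  or a weighted source mixture (admixture), in declaration order. The
  default topology is a star, which is sufficient for every distance-based
  and D/f3 contract.
* **Samples**: diploid genotypes Binomial(2, p); the low-coverage pair by
  gene-dropping under one of four relatedness classes (unrelated,
  parent-offspring, full-sib, identical), Poisson depth, symmetric
  allele-flip sequencing error, optional contamination from a named
  population, optional C-to-T/G-to-A damage applied to endogenous reads at
  transition sites only (modern contaminant reads are deliberately left
  undamaged). Emitted base/mapping qualities always pass the default
  filters, so filtering is exercised by the I/O fixtures instead.
* **Determinism**: one RNG stream per run, seeded from the config; the CLI
  derives per-stage seeds by hashing stage names so inserting a stage never
  perturbs the others.

Two scenario choices deserve a note, both fixed before the test suite was
frozen. For admixture recovery a pure star is unidentifiable -- every
source's f4 profile has the same expectation, making the design matrix
rank-deficient -- so the recovery scenario adds the minimal structure that
identifies it: two of the six rights are sisters of the two sources through
unsampled ancestors (F = 0.05 per branch; sources n = 20, rights n = 15,
target n = 10 -- typical reference-panel population sizes). Sample sizes,
depths (5x for the kinship scenarios) and drift values are in
`tests/testthat/helper-scenarios.R` and are not revisited.

What a green test does **not** establish: the generator has no linkage
disequilibrium within blocks (the jackknife's *raison d'etre* is only
exercised as equal-information blocks), no realistic damage profile along
reads, no indels or mapping artefacts, and panel ascertainment is idealised.
Real-data quantities from degraded samples (absolute CND levels, D Z-scores
against worldwide panels, real admixture proportions) are therefore outside
what the suite can or does claim.

## Numerical choices

* Quality thresholds are inclusive (>= 30 by default) and recorded in
  `filters_applied`; published pipelines are inconsistent between strict
  and inclusive thresholds, so the package fixes one convention and
  exposes it.
* Reads matching neither panel allele are retained and counted but never
  produce calls or enter frequencies (biallelic model).
* `block_partition` requires at least as many usable sites as blocks;
  statistics built on a single block report `NA` standard errors rather
  than failing.
* A zero within-individual distance with a nonzero between-distance makes
  the kinship ratio `indeterminate` (guarded division).
* F = 0 in the generator copies parent frequencies exactly, avoiding the
  degenerate Beta.
* Chi-square df is $m-k$; fits require $m \ge k+1$ and error out otherwise.
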