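---
title: "Models and methods behind cleftgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cleftgwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cleftgwas` implements the statistical machinery of a post-imputation GWAS
workup for a rare, complex binary trait — the motivating application is
nonsyndromic orofacial clefting, where case-control cohorts and ascertained
case-parent trios are analyzed on imputed allele dosages. Because the
genotype data such studies rest on are access-controlled, the package pairs
every analysis stage with a synthetic-cohort generator that has known ground
truth. This vignette records the models, the tunable parameters that matter,
the numerical choices, and what the simulator does and does not emulate.

## The synthetic world

### Haplotypes and linkage disequilibrium

`simulate_panel()` generates binary haplotypes on one synthetic chromosome.
Within each block of `block_size` consecutive variants, a latent Gaussian
AR(1) process with parameter `within_block_correlation` (rho, default 0.8)
is thresholded at the allele-frequency quantile, giving a Gaussian-copula
haplotype model: marginal frequencies are exact, adjacent variants within a
block are correlated (the realized genotype r is somewhat below rho because
dichotomization attenuates the latent correlation), and distinct blocks are
independent. This is the simplest mechanism with a single tunable r^2 and
is sufficient to exercise LD pruning and fine-mapping; it makes no claim to
coalescent realism, recombination hotspots, or any real population's
haplotype structure. Allele frequencies are uniform on `maf_range`
(default 0.05–0.5); positions are evenly spaced, so a flat recombination
map gives closed-form genetic distances for testing the cM windowing.

### Disease models

The default risk model is multiplicative on the odds scale: one copy of the
risk allele at causal variant *j* multiplies the odds by `exp(log_rr[j])`,
with the intercept solved numerically (Monte Carlo + `uniroot`) so the
population prevalence equals `prevalence`. The defaults mirror the target
application: per-locus relative risks around 1.1–1.4 and prevalence 0.001
(0.1%), at which odds ratios and relative risks coincide, consistent with
treating logistic coefficients as log RR throughout. A liability-threshold
variant (`type = "liability"`) places a latent standard-normal liability
with genetic variance `h2` split across causal variants, which is the
natural ground truth for variance-explained recovery experiments.

Cohorts are ascertained by rejection sampling (affected children for trios,
cases until quota for case-control), with a hard draw budget (default 1e7)
so that impossible designs fail loudly rather than spin. Two or more strata
with `stratum_freq_shift` and `stratum_prev_mult` create genuine
population-stratification confounding: allele frequencies and prevalence
both differ by stratum, so unadjusted case-control association inflates
while within-family tests do not. Stratum indicators are returned as
ancestry covariates (the real pipeline would use multidimensional-scaling
axes; the simulator returns the truth those axes estimate).

A practical note used by the test suite: under a null model, affection is
independent of genotype, so the simulated prevalence only changes rejection
sampling runtime, never the distribution of any genotype-based statistic;
under moderate alternatives the same holds to excellent approximation at
prevalence 0.01 (RR ~ OR). Calibration and power suites therefore simulate
at prevalence 0.01–0.1 rather than 0.001. Generator parameters were chosen
once, from these considerations, and are not tuned against test outcomes.

### Imputation-quality degradation

`dosify()` maps hard genotypes to continuous dosages whose realized info
score — the ratio definition `var(dosage) / (2p(1-p))`, the quantity that
QC filters threshold and the only one computable from dosages alone —
matches a target. Genotypes are shrunk toward the variant mean and a small
additive Gaussian component is added; `noise_frac` (default 0.1) sets the
share of dosage variance contributed by noise. The default is deliberately
shrinkage-dominated: imputation posterior means lose information mostly by
regression toward the allele frequency, not by independent scatter, and
this choice preserves association rankings at high info (the package
asserts Spearman >= 0.9 between hard and info-0.9 scans). Clamping to
[0, 2] removes variance, so a short fixed-point iteration rescales around
the mean until the realized info (with the clamped mean) matches the
target; realized info is within ±0.05 of target for n >= 2000.

### Annotation tracks

`simulate_annotation()` places exponential-length intervals either
uniformly or, with probability `anchor_prob`, centred on an associated
variant (by default any variant with P <= `anchor_p`, or an explicit anchor
list). With `anchor_prob = 0` the track is independent of association
signal — the calibration feedstock; raising it creates true enrichment with
a controllable effect. Tracks are normalized: 0-based half-open, sorted,
overlapping or book-ended intervals merged.

## Association testing

`logistic_assoc()` fits, per variant, a logistic regression of status on
dosage plus covariates (and any conditioning dosages), reporting the Wald
beta/SE/Z/two-sided P for the alternate allele — the behaviour of standard
dosage-aware GWAS software. Separated or non-converged fits are flagged
rather than dropped; a tested variant collinear with the conditioning set
(the degenerate case: conditioning a variant on itself) reports beta 0,
P 1, flag `"collinear"`. `method = "score"` computes the covariate-adjusted
Rao score test for all variants from one null fit; it is asymptotically
equivalent under the null and local alternatives and is what the simulation
suites use for genome-wide scans.

The trio statistic treats each parental dosage *d* as an allele-transmission
probability *d*/2: per trio, `U = d_child - (d_father + d_mother)/2` with
variance `(d_f/2)(1-d_f/2) + (d_m/2)(1-d_m/2)`, summed over trios and
standardized. On hard genotypes this reduces *exactly* to the classical TDT
`(b-c)/sqrt(b+c)`, which the tests assert to 1e-8 across random panels; the
published dosage-TDT this emulates prints no formula, so the hard-genotype
equivalence is the anchoring contract. Being a within-family contrast it is
immune to stratification, which the confounded-null experiment demonstrates.

Cohort combination follows the two conventions used in such studies:
weighted Stouffer Z (signed Z from two-sided P and effect direction,
`sum(w z) / sqrt(sum(w^2))`, log-scale for tiny P; the conventional weights
are `sqrt(N_eff)` with `N_eff = 4/(1/N1 + 1/N0)`, configurable because the
original analysis does not print its weights) and fixed-effect
inverse-variance pooling of log RR with Cochran's Q. The genomic inflation
factor is the median association chi-square over `qchisq(0.5, 1)`.

## Credible-SNP refinement

Intervals are defined by genetic distance: the smallest physical interval
whose ends are at least `half_width_cm` (default 0.1 cM) from the index
variant under linear interpolation of the cumulative-cM map, clipped with a
warning at map ends. Per variant, the Wakefield approximate Bayes factor
`sqrt(V/(V+W)) * exp(z^2 W / (2(V+W)))` (V = se^2, W = prior_sd^2, default
prior SD 0.2 on the log-RR scale) is computed on the log scale. Posteriors
are Bayes factors normalized over the interval — implemented as proportion
of the *sum*, since proportion of the mean does not yield probabilities
that sum to one and would contradict aggregating to a >= 95% total.
Variants are ranked by descending posterior with ascending-position
tie-break (determinism), and each credible set is the shortest prefix
reaching its level, hence minimal and nested across levels. The
single-causal assumption is checked by a conditional scan on the index
variant; a conditional P below `secondary_p_threshold` (default 1e-3, the
conventional reporting cut for conditional signals) declares a second
signal, and each signal's set is then computed conditioning on the other's
lead.

## Regulatory-region enrichment

Cis-regulatory modules are assembled combinatorially from peak tracks:
*active* regions are p300/TFAP2A peaks with an H3K27ac peak within 1 kb
(edge-to-edge; overlap is distance 0, and a gap of exactly 1 kb counts as
within); *active and primed* adds H3K27ac peaks overlapping H3K4me1.
Association P-values are binned either into nine ordered categories
`10^(-k+1) >= P > 10^-k` (k = 1..8) plus `P <= 1e-8`, or into the nominal
`P > 0.05` / `P <= 0.05` pair. SNPs (not regions) are counted inside versus
outside the track per category — a variant counts once regardless of how
many intervals cover it — and a one-sided Cochran-Armitage trend test with
equally spaced scores asks whether the inside fraction rises toward smaller
P. The statistic is invariant to affine score changes, so equal spacing is
without loss; the one-sided direction is fixed so that positive Z means
enrichment. Variant positions and track coordinates are compared directly
(`start <= pos < end`); the generator emits both on the same axis.

Two numerical caveats are deliberate. The analytic P is asymptotic while
the permutation distribution of the statistic is a lattice; comparisons
against a permutation oracle therefore use the permutation mid-P. And
calibration experiments rotate across several independent null association
scans rather than fixing one, because 2000 tracks over a single realization
of the P-values confound the lattice discreteness with that realization.

## Polygenic scores

`build_score()` thresholds discovery summary statistics at P_T (the
conventional 11-threshold grid is `pt_grid()`), applies MAF >= 1% and
per-target info >= 0.8 filters, and optionally prunes by greedy LD: walking
variants by ascending P (position tie-break), drop any variant with
r^2 >= 0.25 to an already-kept one. Scores are weighted risk-allele dosage
sums; weights are discovery log RR. In trio targets the affected child is
the case and three pseudo-controls per trio carry the untransmitted
parental allele combinations; on hard genotypes the pseudo-genotype
multiset is well defined even when transmission phase is ambiguous, and
pseudo-individuals are assembled variant-by-variant (the score is additive
and the conditional likelihood only sees scores within a stratum, so
haplotype phase is not required; assignments are randomly permuted per
variant). Unmatched evaluation is logistic regression with a Wald test and
Nagelkerke pseudo-R^2; matched evaluation is conditional logistic
regression (stratified exact Cox form) with the null conditional likelihood
`n log(1/stratum size)` entering the Nagelkerke formula.

The transmitted/non-transmitted score sums, per trio, the weighted child
dosages (transmitted) and `father + mother - child` (non-transmitted) over
a fixed lead-SNP panel; the per-family difference is tested against mean
zero with a two-sided one-sample t-test (the source analysis reports a
mean ± SD and one P without naming its test; with several hundred families
the t-test is the natural choice, and the result object reports the n
actually scored alongside the statistic). The difference is exactly
antisymmetric under swapping the transmitted and non-transmitted labels.

`variance_explained_loci()` fits the joint logistic model on a fixed locus
panel and reports Nagelkerke R^2, the linear-model R^2 on the 0/1 outcome,
and the liability-scale conversion of the latter (Lee et al.
transformation, which needs the assumed prevalence and the sample case
fraction). The conversion is applied to the linear observed-scale R^2
because that is the scale the transformation is derived for; Nagelkerke
R^2 is reported alongside, unconverted. In recovery experiments with a
known 25% liability architecture the pipeline estimate is mildly
conservative (a few points low — ascertainment and the observed-scale
approximation both shave variance), within the ±7-point tolerance the
package asserts.

## What a green test establishes — and what it does not

The simulator provides exchangeable individuals, block-independent LD, a
single chromosome, exact Mendelian trios, and noise-free phenotype labels.
Green calibration and power suites therefore establish that the statistics
are implemented correctly and behave as theory predicts *in that world*.
They do not establish robustness to cryptic relatedness, genotyping batch
effects, imputation reference mismatch, X-chromosome dosage, or real LD
long-range structure — all out of scope. Reported headline numbers from the
motivating study (novel-locus P-values, credible-set sizes at real loci,
enrichment P-values against experimental ChIP-seq maps, GREML variance
components) depend on access-controlled genotypes and external assay data
and are deliberately not implementation targets; the one in-paper
arithmetic target (the Bonferroni cut 0.05/73078) is recomputed by
`scripts/acceptance.R`.

## Degenerate inputs and tie-breaks, in one place

* Monomorphic or uninformative variants: flagged (`"monomorphic"`,
  `"uninformative"`), never silently retained or dropped.
* Separation in logistic fits: infinite-beta sentinel, missing P, flag.
* Collinear tested variant: beta 0, P 1, flag `"collinear"`.
* `P = 0` inputs to Z-combination: rejected (log-scale floor ~1e-308).
* Credible-set ranking ties: ascending position.
* Pruning order ties: ascending position at equal P.
* Empty credible interval, empty reference subset, non-monotone
  recombination maps: rejected with the offending argument named.
* Interval clipping at map ends: warning, not error.
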