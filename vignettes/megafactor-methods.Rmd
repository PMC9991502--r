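---
title: "Sparse-factor whole-genome regression: model, priors, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-factor whole-genome regression: model, priors, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-throughput phenotyping and expression profiling produce hundreds to
tens of thousands of traits per individual. When many of these secondary
traits are genetically or environmentally correlated with a focal trait
(grain yield, flowering time), joint analysis can sharpen both genomic
prediction and association mapping — but a fully parameterized multivariate
mixed model over t traits needs repeated inversions of t x t covariance
matrices and overfits badly. `megafactor` works in the regime where the
trait covariance is generated by a small number of latent factors.

## Model

For n individuals, t traits and p markers,

    Y = X1 B1 + F Lambda + X2R B2R + E_R          (trait level)
    F = X2F B2F + E_F                             (factor level)

* `Y` (n x t) observed traits; missing cells allowed and Gibbs-imputed.
* `F` (n x K) latent factor scores; `Lambda` (K x t) sparse loadings.
* `B2F` (p x K) marker effects on factors, BayesC spike-and-slab per
  element: zero with exclusion probability `piF_k`, else
  `N(0, sigma2_B2F_k)`.
* `Lambda[k, j]` spike-and-slab with exclusion probability `piLambda_k`
  and slab variance `sigma2_R_j / tau_k`, where `tau_k = prod_{h<=k}
  delta_h`, `delta_1 = 1`, `delta_h ~ Gamma(a_delta, b_delta)`. Because
  `tau_k` stochastically increases with k, rows beyond the needed rank
  shrink toward zero and the exact choice of K only costs computation:
  `factorTailCheck()` verifies after the fact that the trailing rows are
  empty, and recommends enlarging K otherwise.
* `B2R` (optional, p x t) trait-specific marker effects, again BayesC per
  trait; it exists only when an `X2R` design is supplied, and its
  exclusion probabilities `piR_j` are sampled only then.
* `E_R` has independent columns with trait residual variances
  `sigma2_R_j ~ Inv-Gamma(a_sigma, b_sigma)`.

Every exclusion probability is an unknown with a Beta(1, 1) prior,
sampled from its conjugate Beta conditional. The `megarrblup` variant pins
all `piF_k = 0` (every marker included), which turns the factor-level
regression into ridge / RR-BLUP; everything else is unchanged.

The focal-trait quantities reported are rotation/sign-invariant
functionals computed per draw: total marker effects
`alphaF = B2F %*% lambda_f`, genetic values `u = X2F %*% alphaF`, and the
empirical variance of `u` across individuals ("genetic variance of the
focal trait"). Posterior means of products are taken per draw, never as
products of posterior means.

## Identifiability and the factor residual scale

Equation two has no free factor-variance parameter: a common scale of `F`
and `1/Lambda` cancels. We therefore fix the factor residual variance at 1
and let `Lambda` absorb the scale. The one exception is a factor whose
loading row is entirely *fixed* (see below): there the scale is pinned by
the fixed loadings, so fixing its residual variance too would force the
focal trait to carry at least unit residual variance regardless of its
scale. For such rows the factor residual variance is sampled from its
Inv-Gamma conditional instead. This keeps the pinned-factor construction
exact at any trait scale; it is the package's own resolution of a
degeneracy the model statement leaves open.

## The fixed first factor

For prediction-style fits, `megaHyper(fixedFocalFactor = TRUE)` pins the
first loading row to the focal-trait unit vector (1 on the focal trait, 0
elsewhere). Markers in the first factor then act on the focal trait
directly, while the remaining factors route information from the secondary
traits. Fixed entries are never updated, are excluded from the
shrinkage/Beta bookkeeping, and survive arbitrarily long chains unchanged.

## Gibbs sweep

One systematic scan updates, in order: (a) fixed effects (flat prior,
normal conditionals); (b) free loadings by single-site spike-slab updates;
(c) loading exclusion probabilities (Beta); (d) shrinkage increments
`delta_h` (Gamma conditionals of the cumulative-product prior); (e) factor
scores jointly per individual (K-dimensional normal); (f) factor marker
effects by single-site spike-slab updates; (g) marker-effect variances
(scaled-Inv-chi-square conditionals) and `piF`; (h) optional trait-specific
marker effects and their hyperparameters; (i) trait residual variances
(Inv-Gamma, including the loading-slab contribution since the slab scales
with `sigma2_R_j`); (j) missing trait cells from their predictive normal.
The per-iteration log joint is tracked and must stay finite; a non-finite
value aborts with the iteration index.

The marker scans are the cost center. For p up to 3000 the sampler
precomputes `X'X` once and maintains the vector of marker-residual inner
products under coefficient changes, which reads p-vectors instead of
n-vectors per site; beyond that it falls back to direct residual updates.
Both paths implement the same conditionals.

A single-coefficient reference implementation, `spikeSlabUpdate()`, is
exported; its inclusion probability is checked against the closed-form
two-component posterior in the tests. A zero-variance covariate yields a
likelihood ratio of exactly 1, so the indicator falls back to the prior
odds and an excluded coefficient is exactly 0 — the same convention at
every site of the samplers.

## Hyperparameter defaults

| parameter | default | meaning |
|---|---|---|
| `a_delta, b_delta` | 2, 1 | shrinkage increments; E[tau_k] grows ~2^k |
| `a_sigma, b_sigma` | 1, 1 | Inv-Gamma on residual variances |
| Beta on every pi | (1, 1) | uniform prior on exclusion probabilities |
| marker-effect df | 4 | scaled-Inv-chi-square df |
| marker-effect scale | matched | half a standardized trait variance spread over the expected number of included markers times the mean marker variance |

Traits are centered and standardized internally (`scaleY = TRUE`), and all
focal-trait outputs are returned on the original scale; loadings are
reported on the standardized-trait scale. Initialization is the truncated
rank-K SVD of the column-standardized observed trait matrix (missing cells
mean-filled for the decomposition only) — deterministic given the seed and
fast-mixing in practice. All chain randomness flows through R's RNG, so a
single integer seed makes runs bit-reproducible.

## Baselines and the two-stage pipeline

`stBayesC()` is the univariate BayesC baseline (same spike-slab kernel,
shared slab variance, sampled pi). `gwasScan()` is the single-marker scan:
ordinary least squares by default, or an EMMAX-style generalized
least-squares mode with a VanRaden-GRM variance component estimated once on
the null model. The scan exists to rank markers for preselection; it makes
no attempt to replicate any specific external GWAS program's REML
internals, and both modes are provided because either can be the
appropriate stand-in depending on population structure.

`runTwoStage()` implements the preselection pipeline: a scan on the
focal-only partition, greedy clumping (`clumpSelect()`: survivors with
P <= 0.01, repeatedly take the most significant and mask everything within
+/-250 kb with r^2 > 0.5 — ties broken by position then id, so the result
is input-order invariant), then the Bayesian model on the other partition
restricted to the candidates. Stage-2 MegaBayesC uses the fixed-first-factor
construction by default so candidates can act on the focal trait directly.
Markers never selected carry an implicit effect of zero, which is also how
the truth-aware scoring (`scoreEstimates()`) treats QTL missed entirely;
QTL represented only by a linked proxy (r^2 > 0.4) are flagged, because a
negative linkage phase flips the sign of the estimated effect while its
explained variance stays comparable — hence the two RMSEs (signed effects,
explained SDs) reported separately.

## Prediction and cross-validation

`vanRadenGRM()` and `reflectanceKernel()` build the genomic and
secondary-trait kernels; `gblupFit()` estimates variance components by
direct REML (log-variance parameterization, L-BFGS-B with three dispersed
restarts — with one kernel the problem is one-dimensional and benign, with
two the restarts guard against the occasional ridge in the likelihood) and
returns BLUPs for all samples including masked ones. With an identity
kernel the variance split is not identifiable from REML — the likelihood
depends only on the total — so closed-form checks pin the components via
`fixedVarComp`.

Masked cross-validation (`makeCvPlan()`) hides the focal trait of a random
half of the samples; secondary traits of masked samples stay observed,
exactly because letting them inform prediction is the point of the
multivariate model. That choice biases the naive correlation between
predictions and observed phenotypes, so accuracy is reported as
`cor(u_hat, y_test) / sqrt(h2_focal)` (`correctedAccuracy()`), with the
heritability taken from the training fit unless supplied. The literature
offers several corrected estimators; the square-root-of-heritability form
is the standard one and is used here deliberately — it is exact when the
prediction error is independent of the genetic value. Because CV
repetitions re-use validation data, method comparisons use the
resampling-adjusted t statistic `mean(d)/sqrt((1/reps + n2/n1) var(d))`
(`adjustedT()`), which is never larger in magnitude than the classical t.

## Simulators

`simIndependentGenotypes()` draws dosages i.i.d. uniform on {0, 1, 2}:
no linkage, no structure, allele frequency 1/2 everywhere. The
factor-scenario generator (`simFactorScenario()`) builds the loading
pattern with `buildLambda()` (focal trait loads 1 on every factor; each
factor owns a dedicated block of secondary traits), assigns each factor
`nqtlPerFactor` QTL drawn without replacement within a factor but
independently across factors (so a marker can hit several factors), with
all effects of magnitude 0.1 and random sign. In scenario 1 every factor
is genetic with the QTL explaining 95% of its variance; in scenario 2 only
factor 1 is, and the remaining factors are pure noise matched to factor
1's total variance so all factors contribute equally to the focal trait.
Trait-specific noise is 10% of each trait's variance. With these choices
the focal trait's genetic share is exactly `0.95 * 0.9 * (#genetic
factors) / nfactor` in the generator's (genotype-fixed) bookkeeping —
14.25% for scenario 2 with six factors, 9.5% with nine — and the per-QTL
explained shares scale inversely with the total QTL count. The fixed 0.1
effect magnitude makes the absolute effect scale reproducible; only the
noise scales adapt to the share targets.

`simLdGenotypes()` is an explicitly synthetic stand-in for a structured
population: haplotype alleles follow a first-order Markov chain along the
chromosome (adjacent-allele correlation `rho`, so adjacent r^2 is about
`rho^2`), allele frequencies are drawn from `mafRange`, and two haplotypes
are summed per individual. It reproduces local LD decay and variable
allele frequencies; it does **not** reproduce long-range structure,
demography, or real LD block architecture, so any conclusion that depends
on genome-scale LD (for example the roughly ten-fold RMSE gap between
one-stage and two-stage analyses reported on real resequencing panels)
is out of desk scale here and only its qualitative direction is checked.
Re-running the two-stage-versus-one-stage comparison on a real genotype
panel is the natural full-scale follow-up; the pipeline accepts any panel
through `readGenotypeTable()`.

`simArabidopsisLike()` mimics the many-trait eQTL-style design: markers
LD-pruned (r^2 0.8, 500-marker windows sliding by 100) so 20 QTL can be
drawn quasi-independent; 10 factors, 2 distinct QTL each, effect
magnitudes U(3, 5) with a random half negated; the focal trait loads 0.5
on every factor, each factor loads 1 on 20 dedicated secondary traits (201
traits total); focal heritability 0.6, secondary heritabilities 0.8;
factors carry no residual, so all genetic variance flows through the QTL.
A fraction 649/1003 of samples carries secondary records, the rest only
the focal trait — the partition the two-stage pipeline consumes.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive bp; the gene-matching window is
  inclusive on both ends (`[start - 100kb, end + 100kb]`).
* QC thresholds follow the stated inequality directions exactly: MAF <=
  0.05 removed, missing rate >= 0.1 removed (Arabidopsis rule), call rate
  <= 50% removed (wheat rule, which then mean-imputes). Both rules are
  idempotent. The call-rate definition is per-marker; a per-sample reading
  would interact with sample alignment and is not what a marker-QC step
  does.
* Significance rules are strict: explained proportion > 0.001;
  P < 1e-5. A proportion of exactly 0.001 is not significant.
* Monomorphic markers: r^2 defined as 0; scan estimate 0 with P = 1;
  spike-slab indicator from prior odds.
* `adjustedT()` with zero variance returns signed infinity (0 for an
  identically-zero difference vector) rather than NaN.
* Chain length bookkeeping: stored draws = `floor((nIter - burnin)/thin)`.

## Problem sizes used in the shipped checks

The test suite exercises the samplers at sizes chosen to make each
scientific property measurable while keeping a full run comfortable on a
single CPU: the scenario-grid generator runs at its native n = 3000,
p = 2000; the diffuse-architecture comparison of the multivariate model
against univariate BayesC runs at n = 1500 with 4000-iteration chains and
five seeds; heritability recovery on the Arabidopsis-like design runs at
n = 600 with K = 15. These sizes are the package's own choices for its
regression suite; the functions themselves carry no such limits.

## Known limitations

* Single-site marker updates mix slowly when markers are in very strong
  mutual LD; the two-stage pipeline (clumping first) is the intended use
  for dense panels.
* The `X'X` fast path holds a p x p matrix; above p = 3000 the sampler
  switches to residual updates and slows accordingly.
* GBLUP-with-GRM as a *random-effect parameterization inside the factor
  model* is not implemented; `megarrblup` covers the equivalent
  whole-genome ridge formulation, and `gblupFit()` provides the standalone
  kernel baselines.
* BayesA/BayesB/BayesR-style slabs are not implemented; the kernel is
  deliberately the two-component BayesC mixture.
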