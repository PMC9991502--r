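# megafactor

Bayesian sparse-factor whole-genome regression for genomic prediction and
association when one focal trait (grain yield, flowering time, ...) comes
with hundreds to thousands of correlated secondary traits (hyperspectral
bands, gene expression). Fitting a full multivariate mixed model over t
traits is cubic-to-quintic in t; `megafactor` instead assumes the trait
covariance is generated by K << t latent factors and puts the
whole-genome regression on the factors:

    Y = X1 B1 + F Λ + X2R B2R + E_R
    F = X2F B2F + E_F

with BayesC spike-and-slab priors on the marker effects `B2F` (point mass
at zero with exclusion probability π, else a shared-variance normal slab)
and on the loadings `Λ` (slab variance `σ²_Rj / τ_k`, with `τ_k` a
cumulative product of Gamma increments that shrinks trailing factor rows
to zero). Total marker effects on the focal trait are `α_f = B2F λ_f`,
genetic values `u = X2F α_f`, both computed per MCMC draw. Setting every
marker exclusion probability to zero gives the ridge variant
(`megarrblup`), the whole-genome-regression equivalent of GBLUP.

Around the core model: a univariate BayesC baseline and single-marker
scan, a two-stage pipeline (scan on a focal-only partition, greedy LD
clumping, then the multivariate model on the preselected candidates),
VanRaden-GRM / secondary-trait kernels with one- and two-kernel GBLUP,
masked cross-validation with heritability-corrected accuracy and a
resampling-adjusted t statistic, rank-normalized split R-hat and
factor-tail diagnostics, and simulators for factor-structured phenotypes
on independent or LD-patterned genotypes.

## Worked example

Simulate a diffuse architecture in which only one of nine latent factors
is genetic (so most trait correlations are environmental), then compare
the multivariate fit with univariate BayesC:

```r
library(megafactor)

G   <- simIndependentGenotypes(n = 1500, p = 2000, seed = 101)
sim <- simFactorScenario(G, list(scenario = 2, nfactor = 9,
                                 ntraitPerFactor = 2, nqtlPerFactor = 30,
                                 seed = 102))
y   <- phenoValues(sim$phenotypes)[, 1]

ch <- runMcmc(G, sim$phenotypes, megaHyper(K = 10),
              nIter = 4000, burnin = 1000, thin = 5, seed = 103)
aMega <- focalMarkerEffects(ch)

st  <- stBayesC(y, G, nIter = 4000, burnin = 1000, thin = 5, seed = 104)
isQ <- sim$truth$alphaF != 0
rmse <- function(a) sqrt(mean((a[isQ] - sim$truth$alphaF[isQ])^2))
cat("QTL rmse mega:", rmse(aMega), " st:", rmse(st$effects), "\n")
cat("null range mega:", diff(range(aMega[!isQ])),
    " st:", diff(range(st$effects[!isQ])), "\n")
```

Output from this exact script:

```
QTL rmse mega: 0.007705252  st: 0.08689821
null range mega: 0.04368685  st: 0.09011525
```

All 270 QTL have true effect 0.1 on the focal trait. The univariate model
shrinks most of them away (RMSE ≈ 0.087, close to the 0.1 it would get by
estimating zero everywhere) and scatters null-marker estimates over a
visibly wider range; the factor model uses the 17 secondary traits to
separate the genetic factor from the environmental ones and recovers the
effects an order of magnitude more accurately.

## Layout

* `R/`, `src/` — package code; the Gibbs samplers are in
  `src/samplers.cpp`.
* `tests/testthat/` — unit, property and end-to-end suites (fixtures are
  generated in code).
* `vignettes/megafactor-methods.Rmd` — the model, priors, samplers,
  simulators, numerical conventions and design rationale.
* `inst/scripts/megafactor.R` — thin command-line front end
  (`simulate`, `filter`, `scan`, `fit`, `two-stage`).
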