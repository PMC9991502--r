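#' Spike-and-slab (BayesC) site update
#'
#' Reference implementation of the single-coefficient mixture update used
#' throughout the samplers. Given the residual with the coefficient's own
#' contribution added back (\code{yRes}), its covariate \code{x}, the noise
#' variance, slab variance and exclusion probability, the inclusion
#' indicator is drawn from its Bernoulli full conditional (the marginal
#' likelihood ratio of slab vs spike times the prior odds) and, if included,
#' the coefficient from its conjugate normal conditional
#' \code{N(x'y / (x'x + s2e/s2b), s2e / (x'x + s2e/s2b))}. Excluded
#' coefficients are exactly 0. A zero-variance covariate gives a likelihood
#' ratio of exactly 1, so the indicator follows the prior odds.
#'
#' @param yRes residual vector including this coefficient's contribution
#' @param x covariate vector
#' @param sigma2E noise variance (> 0)
#' @param sigma2B slab variance (> 0)
#' @param pi exclusion probability in [0, 1]
#' @return list with \code{coefficient}, \code{indicator},
#'   \code{probInclude}, and the conditional slab \code{mean} and \code{var}
#' @export
spikeSlabUpdate <- function(yRes, x, sigma2E, sigma2B, pi) {
  stopIfNot(sigma2E > 0 && sigma2B > 0, "variances must be positive")
  stopIfNot(pi >= 0 && pi <= 1, "pi must be in [0, 1]")
  xtx <- sum(x^2)
  xty <- sum(x * yRes)
  v <- 1 / (xtx / sigma2E + 1 / sigma2B)
  m <- v * xty / sigma2E
  if (pi >= 1) {
    pIncl <- 0
  } else if (pi <= 0) {
    pIncl <- 1
  } else {
    logBF <- 0.5 * log(v / sigma2B) + 0.5 * m^2 / v
    pIncl <- 1 / (1 + exp(-(log1p(-pi) - log(pi) + logBF)))
  }
  ind <- as.integer(stats::runif(1) < pIncl)
  coef <- if (ind == 1) stats::rnorm(1, m, sqrt(v)) else 0
  list(coefficient = coef, indicator = ind, probInclude = pIncl,
       mean = m, var = v)
}

#' Posterior total marker effects on the focal trait
#'
#' The per-draw product \code{B2F \%*\% lambda_f} (lambda_f = column of the
#' loading matrix for the focal trait) is accumulated during sampling;
#' this returns its posterior mean (never the product of posterior means),
#' optionally the per-marker posterior SD or the raw draws.
#'
#' @param chain a \linkS4class{MegaChain}
#' @param summary \code{"mean"}, \code{"sd"} or \code{"draws"}
#' @return named numeric vector (or markers x draws matrix)
#' @export
focalMarkerEffects <- function(chain, summary = c("mean", "sd", "draws")) {
  summary <- match.arg(summary)
  a <- chain@draws$alphaF
  if (length(chain@markerIds) == nrow(a)) rownames(a) <- chain@markerIds
  switch(summary,
         mean = rowMeans(a),
         sd = apply(a, 1, stats::sd),
         draws = a)
}

#' Predicted genetic values of the focal trait
#'
#' \code{u = X2F \%*\% alphaF} with \code{alphaF} the per-draw product
#' averaged over draws (linearity makes the two orders identical). With
#' \code{X2F = NULL} the genetic values of the training samples are
#' returned.
#'
#' @param chain a \linkS4class{MegaChain}
#' @param X2F optional dosage matrix or \linkS4class{GenotypeMatrix} whose
#'   columns must match the chain's marker set
#' @return named numeric vector of genetic values
#' @export
predictGeneticValues <- function(chain, X2F = NULL) {
  if (is.null(X2F)) return(chain@posteriorMeans$u)
  if (is(X2F, "GenotypeMatrix")) X2F <- dosages(X2F)
  stopIfNot(ncol(X2F) == length(chain@markerIds),
            "marker count mismatch between X2F and chain")
  if (!is.null(colnames(X2F)) && length(chain@markerIds) &&
      !identical(colnames(X2F), chain@markerIds))
    stop("marker ids of X2F do not match the chain", call. = FALSE)
  drop(X2F %*% chain@posteriorMeans$alphaF)
}

#' Per-draw genetic variance of the focal trait
#'
#' For each stored draw, the empirical variance across individuals of the
#' genetic-value vector \code{X2F B2F lambda_f}. These draws are the default
#' functional for R-hat convergence checks.
#'
#' @param chain a \linkS4class{MegaChain}
#' @param X2F optional dosage matrix (defaults to the training genotypes'
#'   stored genetic values; requires \code{storeU = TRUE} draws when given)
#' @return numeric vector, one variance per stored draw
#' @export
geneticVarianceSamples <- function(chain, X2F = NULL) {
  if (is.null(X2F)) return(chain@draws$genVar)
  if (is(X2F, "GenotypeMatrix")) X2F <- dosages(X2F)
  a <- chain@draws$alphaF
  stopIfNot(ncol(X2F) == nrow(a), "marker count mismatch between X2F and chain")
  apply(X2F %*% a, 2, stats::var)
}
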