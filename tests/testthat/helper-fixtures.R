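# Shared fixture builders. Everything is generated in code; no data files.

# Minimal valid sampler state, for assembling synthetic chains.
toyState <- function() {
  new("FactorModelState",
      F = matrix(0, 1, 1), Lambda = matrix(0, 1, 1),
      LambdaInd = matrix(0, 1, 1), B1 = matrix(0, 1, 1),
      B2F = matrix(0, 1, 1), B2FInd = matrix(0, 1, 1),
      B2R = matrix(0, 0, 0), B2RInd = matrix(0, 0, 0),
      sigma2R = 1, sigma2B2F = 1, sigma2B2R = numeric(0), sigma2F = 1,
      delta = 1, piLambda = 0.5, piF = 0.5, piR = numeric(0),
      Ywork = matrix(0, 1, 1))
}

# A synthetic posterior chain with prescribed alphaF (p x d) and Lambda
# (K*t x d) draws; enough structure for the posterior-summary functions.
toyChain <- function(alphaF, X2F = NULL, Lambda = NULL, K = 1,
                     traitIds = character(0)) {
  d <- ncol(alphaF)
  u <- if (is.null(X2F)) matrix(0, 1, d) else X2F %*% alphaF
  draws <- list(alphaF = alphaF,
                genVar = apply(u, 2, stats::var),
                logJoint = rep(0, d))
  if (!is.null(Lambda)) draws$Lambda <- Lambda
  pm <- list(alphaF = rowMeans(alphaF),
             u = rowMeans(u),
             Lambda = if (is.null(Lambda)) NULL else
               matrix(rowMeans(Lambda), K, nrow(Lambda) / K))
  new("MegaChain", draws = draws, posteriorMeans = pm,
      settings = list(nIter = d, burnin = 0, thin = 1, seed = 1L,
                      variant = "megabayesc", K = K),
      markerIds = paste0("m", seq_len(nrow(alphaF))),
      traitIds = traitIds, focal = 1L, finalState = toyState())
}

# Genotype matrix from explicit dosages with default map.
toyGenotypes <- function(d, ...) GenotypeMatrix(as.matrix(d), ...)
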