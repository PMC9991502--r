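#' Hyperparameters of the sparse-factor model
#'
#' Collects every tunable prior setting. Defaults: delta ~ Gamma(2, 1) so the
#' cumulative-product shrinkage tau_k stochastically increases along factors;
#' residual variances ~ Inv-Gamma(1, 1); every exclusion probability ~
#' Beta(1, 1); marker-effect variances ~ scaled-Inv-chi-square(df = 4, scale
#' matched to half the (standardized) trait variance spread over the expected
#' number of included markers). Any of these can be overridden.
#'
#' @param K number of latent factors (>= 0; 0 drops the factor block
#'   entirely, leaving fixed effects plus optional trait-specific marker
#'   effects)
#' @param aDelta,bDelta Gamma shape/rate for the shrinkage increments
#'   delta_h (h >= 2; delta_1 = 1)
#' @param aSigma,bSigma Inv-Gamma shape/rate for trait residual variances
#'   (and for factor residual variances of factors with a fully fixed
#'   loading row)
#' @param piLambdaBeta,piFBeta,piRBeta length-2 Beta parameters for the
#'   loading, factor-marker and trait-marker exclusion probabilities
#' @param markerEffectDf scaled-Inv-chi-square df for marker-effect variances
#' @param markerEffectScale its scale; NULL = matched to the data (see
#'   Description)
#' @param fixedLoadings optional K x t numeric matrix: non-NA entries pin the
#'   corresponding loadings permanently (never updated)
#' @param fixedFocalFactor convenience switch: pin the first factor's loading
#'   row to the focal-trait unit vector (1 on the focal trait, 0 elsewhere)
#'   so markers in that factor act on the focal trait directly; requires
#'   \code{nTraits}
#' @param nTraits trait count, only needed by \code{fixedFocalFactor}
#' @param fixPiF,fixPiLambda pin exclusion probabilities to a constant
#'   instead of sampling them (the ridge variant pins \code{fixPiF = 0})
#' @param fixSigma2R,fixSigma2B2F,fixSigma2F pin variance parameters
#'   (vectors recycled to length t / K / K); mainly for oracle checks
#' @param scaleY center and scale traits internally (outputs are returned on
#'   the original scale); default TRUE
#' @return a list of class \code{"megaHyper"}
#' @export
megaHyper <- function(K, aDelta = 2, bDelta = 1, aSigma = 1, bSigma = 1,
                      piLambdaBeta = c(1, 1), piFBeta = c(1, 1),
                      piRBeta = c(1, 1), markerEffectDf = 4,
                      markerEffectScale = NULL, fixedLoadings = NULL,
                      fixedFocalFactor = FALSE, nTraits = NULL,
                      fixPiF = NULL, fixPiLambda = NULL,
                      fixSigma2R = NULL, fixSigma2B2F = NULL,
                      fixSigma2F = NULL, scaleY = TRUE) {
  stopIfNot(K >= 0, "K must be >= 0")
  stopIfNot(all(c(aDelta, bDelta, aSigma, bSigma) > 0),
            "prior shapes/rates must be positive")
  if (fixedFocalFactor) {
    stopIfNot(K >= 1, "fixedFocalFactor needs K >= 1")
    stopIfNot(!is.null(nTraits), "fixedFocalFactor needs nTraits")
  }
  structure(list(
    K = as.integer(K), aDelta = aDelta, bDelta = bDelta,
    aSigma = aSigma, bSigma = bSigma,
    piLambdaBeta = piLambdaBeta, piFBeta = piFBeta, piRBeta = piRBeta,
    markerEffectDf = markerEffectDf, markerEffectScale = markerEffectScale,
    fixedLoadings = fixedLoadings, fixedFocalFactor = fixedFocalFactor,
    nTraits = nTraits, fixPiF = fixPiF, fixPiLambda = fixPiLambda,
    fixSigma2R = fixSigma2R, fixSigma2B2F = fixSigma2B2F,
    fixSigma2F = fixSigma2F, scaleY = scaleY), class = "megaHyper")
}

# Resolve the fixed-loading pattern into a K x t numeric matrix (NA = free).
resolveFixedLoadings <- function(hyper, t, focal) {
  K <- hyper$K
  fl <- hyper$fixedLoadings
  if (is.null(fl)) fl <- matrix(NA_real_, K, t)
  stopIfNot(nrow(fl) == K && ncol(fl) == t,
            "fixedLoadings must be K x t")
  if (hyper$fixedFocalFactor) {
    fl[1, ] <- 0
    fl[1, focal] <- 1
  }
  fl
}
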