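#' Assemble the internal model data for the sparse-factor sampler
#'
#' Aligns genotypes and phenotypes on sample ids, optionally standardizes the
#' traits (column mean/sd over observed cells; an all-missing or constant
#' column gets mean 0 / scale 1) and builds the design matrices. Genotypes
#' must be fully observed (impute first, e.g. [filterMarkers()] with the
#' wheat rule).
#'
#' @param genotypes a \linkS4class{GenotypeMatrix} (or plain dosage matrix)
#' @param phenotypes a \linkS4class{PhenotypeBlock} (or plain trait matrix
#'   with NA = missing; first column focal)
#' @param hyper a [megaHyper()] object
#' @param X1 fixed-effect design; NULL = intercept only
#' @param X2R optional trait-specific marker design
#'   (\linkS4class{GenotypeMatrix} or matrix)
#' @return list with standardized \code{Y}, mask, designs, focal index,
#'   trait centers/scales and ids — the \code{data} argument of
#'   [initializeState()] and [gibbsSweep()]
#' @export
megaModelData <- function(genotypes, phenotypes, hyper, X1 = NULL,
                          X2R = NULL) {
  if (is(genotypes, "GenotypeMatrix")) {
    stopIfNot(!any(missingMask(genotypes)),
              "genotype dosages must be fully observed; impute first")
    X2F <- dosages(genotypes)
  } else X2F <- as.matrix(genotypes)
  if (!is(phenotypes, "PhenotypeBlock"))
    phenotypes <- PhenotypeBlock(as.matrix(phenotypes))
  Y <- phenoValues(phenotypes)
  if (!is.null(rownames(Y)) && !is.null(rownames(X2F))) {
    idx <- match(rownames(X2F), rownames(Y))
    stopIfNot(!anyNA(idx), "sample ids of genotypes and phenotypes must align")
    Y <- Y[idx, , drop = FALSE]
  }
  stopIfNot(nrow(Y) == nrow(X2F), "sample counts must agree")
  miss <- is.na(Y)
  bad <- !miss & !is.finite(Y)
  stopIfNot(!any(bad), "non-finite trait values outside the missing mask")
  n <- nrow(Y); t <- ncol(Y)
  if (hyper$scaleY) {
    ctr <- colMeans(Y, na.rm = TRUE)
    scl <- apply(Y, 2, stats::sd, na.rm = TRUE)
    ctr[!is.finite(ctr)] <- 0
    scl[!is.finite(scl) | scl == 0] <- 1
  } else {
    ctr <- rep(0, t); scl <- rep(1, t)
  }
  Ys <- sweep(sweep(Y, 2, ctr), 2, scl, "/")
  Ys[miss] <- 0  # starting imputation at the trait mean
  if (is.null(X1)) X1 <- matrix(1, n, 1)
  if (!is.null(X2R) && is(X2R, "GenotypeMatrix")) X2R <- dosages(X2R)
  if (is.null(X2R)) X2R <- matrix(0, n, 0)
  list(Y = Ys, Ymiss = miss, X1 = as.matrix(X1), X2F = X2F,
       X2R = as.matrix(X2R), focal = focalIndex(phenotypes),
       center = ctr, scale = scl,
       markerIds = colnames(X2F), traitIds = colnames(Y))
}

# Default scaled-Inv-chi-square scale for marker-effect variances: half a
# (standardized) unit of variance divided over the expected number of
# included markers times the mean marker variance.
markerEffectScaleDefault <- function(X, pi0) {
  p <- ncol(X)
  if (p == 0) return(1)
  mv <- mean(colVars(X))
  if (!is.finite(mv) || mv <= 0) mv <- 1
  nIncl <- max(1, p * (1 - pi0))
  0.5 / (nIncl * mv)
}

#' Initialize a Gibbs state
#'
#' Factors and loadings start from the truncated rank-K SVD of the
#' column-standardized observed trait matrix (missing cells mean-filled for
#' the decomposition only), scaled so factor columns have unit variance;
#' marker and fixed effects start at zero; variances start at prior-typical
#' values; inclusion indicators of the (zero) marker effects are drawn from
#' the initial exclusion probabilities; the fixed-loading pattern is applied
#' and never altered afterwards.
#'
#' @param data from [megaModelData()]
#' @param hyper a [megaHyper()] object
#' @param seed integer seed or NULL
#' @return a \linkS4class{FactorModelState}
#' @export
initializeState <- function(data, hyper, seed = NULL) {
  n <- nrow(data$Y); t <- ncol(data$Y)
  K <- hyper$K
  stopIfNot(K <= min(n, t), "K must not exceed min(n, t)")
  p <- ncol(data$X2F); pR <- ncol(data$X2R)
  fl <- resolveFixedLoadings(hyper, t, data$focal)
  withSeed(seed, {
    piF0 <- if (is.null(hyper$fixPiF)) {
      hyper$piFBeta[1] / sum(hyper$piFBeta)
    } else hyper$fixPiF
    piL0 <- if (is.null(hyper$fixPiLambda)) {
      hyper$piLambdaBeta[1] / sum(hyper$piLambdaBeta)
    } else hyper$fixPiLambda
    piR0 <- hyper$piRBeta[1] / sum(hyper$piRBeta)
    if (K > 0) {
      Yinit <- data$Y
      sdv <- apply(Yinit, 2, stats::sd)
      sdv[!is.finite(sdv) | sdv == 0] <- 1
      Yinit <- sweep(sweep(Yinit, 2, colMeans(Yinit)), 2, sdv, "/")
      sv <- svd(Yinit, nu = K, nv = K)
      Fm <- sv$u * sqrt(n - 1)
      L <- diag(sv$d[seq_len(K)], K) %*% t(sv$v) / sqrt(n - 1)
      LInd <- matrix(1, K, t)
      fixed <- !is.na(fl)
      L[fixed] <- fl[fixed]
      LInd[fixed] <- as.numeric(fl[fixed] != 0)
      delta <- c(1, rep(hyper$aDelta / hyper$bDelta, K - 1))
    } else {
      Fm <- matrix(0, n, 0); L <- matrix(0, 0, t); LInd <- matrix(0, 0, t)
      delta <- numeric(0)
    }
    s2b <- if (is.null(hyper$markerEffectScale)) {
      markerEffectScaleDefault(data$X2F, if (length(piF0)) piF0[1] else 0.5)
    } else hyper$markerEffectScale
    sigma2B2F <- rep(if (is.null(hyper$fixSigma2B2F)) s2b else
                       hyper$fixSigma2B2F, length.out = max(K, 1))[seq_len(K)]
    freeRow <- if (K > 0) apply(!is.na(fl), 1, all) else logical(0)
    sigma2F <- rep(1, K)
    if (!is.null(hyper$fixSigma2F))
      sigma2F <- rep(hyper$fixSigma2F, length.out = K)
    sigma2R <- rep(if (is.null(hyper$fixSigma2R)) 0.5 else hyper$fixSigma2R,
                   length.out = t)
    s2bR <- markerEffectScaleDefault(data$X2R, piR0)
    new("FactorModelState",
        F = Fm, Lambda = L, LambdaInd = LInd,
        B1 = matrix(0, ncol(data$X1), t),
        B2F = matrix(0, p, K),
        B2FInd = matrix(stats::rbinom(p * K, 1, 1 - mean(piF0)), p, K),
        B2R = matrix(0, pR, t * (pR > 0)),
        B2RInd = matrix(stats::rbinom(pR * t * (pR > 0), 1, 1 - piR0),
                        pR, t * (pR > 0)),
        sigma2R = sigma2R, sigma2B2F = sigma2B2F,
        sigma2B2R = rep(s2bR, if (pR > 0) t else 0),
        sigma2F = sigma2F, delta = delta,
        piLambda = rep(piL0, length.out = K),
        piF = rep(piF0, length.out = K),
        piR = rep(piR0, if (pR > 0) t else 0),
        Ywork = data$Y)
  })
}

# Shared driver: run `nIter` sweeps from `state`, return raw C++ output.
runSampler <- function(state, data, hyper, nIter, burnin, thin, storeU,
                       variant) {
  K <- hyper$K
  t <- ncol(data$Y)
  fl <- resolveFixedLoadings(hyper, t, data$focal)
  fixedMask <- matrix(as.integer(!is.na(fl)), max(K, 1), t)[seq_len(K), ,
                                                            drop = FALSE]
  freeS2F <- if (K > 0) as.integer(apply(fixedMask == 1, 1, all) &
                                     is.null(hyper$fixSigma2F)) else integer(0)
  samplePiF <- is.null(hyper$fixPiF) && variant != "megarrblup"
  s2bR <- if (length(state@sigma2B2R)) state@sigma2B2R else numeric(0)
  mega_gibbs_cpp(
    Y = state@Ywork, Ymiss = matrix(as.integer(data$Ymiss), nrow(data$Y)),
    X1 = data$X1, X2F = data$X2F, X2R = data$X2R,
    F = state@F, Lambda = state@Lambda,
    LambdaInd = matrix(as.integer(state@LambdaInd), K, t),
    B1 = state@B1, B2F = state@B2F,
    B2FInd = matrix(as.integer(state@B2FInd), ncol(data$X2F), K),
    B2R = state@B2R,
    B2RInd = matrix(as.integer(state@B2RInd), nrow(state@B2RInd),
                    ncol(state@B2RInd)),
    sigma2R = state@sigma2R, sigma2B2F = state@sigma2B2F,
    sigma2B2R = s2bR, sigma2F = state@sigma2F, delta = state@delta,
    piLambda = state@piLambda, piF = state@piF, piR = state@piR,
    LambdaFixed = fixedMask, freeSigma2F = freeS2F,
    aDelta = hyper$aDelta, bDelta = hyper$bDelta,
    aSigma = hyper$aSigma, bSigma = hyper$bSigma,
    piLambdaA = hyper$piLambdaBeta[1], piLambdaB = hyper$piLambdaBeta[2],
    piFA = hyper$piFBeta[1], piFB = hyper$piFBeta[2],
    piRA = hyper$piRBeta[1], piRB = hyper$piRBeta[2],
    nuB2F = hyper$markerEffectDf,
    scaleB2F = rep({
      if (!is.null(hyper$markerEffectScale)) hyper$markerEffectScale
      else {
        pi0 <- if (variant == "megarrblup") 0
               else if (!is.null(hyper$fixPiF)) hyper$fixPiF else 0.5
        markerEffectScaleDefault(data$X2F, pi0)
      }
    }, length.out = max(K, 1))[seq_len(K)],
    nuB2R = hyper$markerEffectDf,
    scaleB2R = if (length(s2bR)) s2bR else numeric(0),
    samplePiF = samplePiF,
    samplePiLambda = is.null(hyper$fixPiLambda),
    sampleSigma2R = is.null(hyper$fixSigma2R),
    sampleSigma2B2F = is.null(hyper$fixSigma2B2F),
    focal = data$focal - 1L, nIter = nIter, burnin = burnin, thin = thin,
    storeU = storeU)
}

stateFromList <- function(fs, K, t) {
  new("FactorModelState",
      F = fs$F, Lambda = matrix(fs$Lambda, K, t),
      LambdaInd = matrix(fs$LambdaInd, K, t),
      B1 = fs$B1, B2F = fs$B2F, B2FInd = fs$B2FInd,
      B2R = fs$B2R, B2RInd = fs$B2RInd,
      sigma2R = as.numeric(fs$sigma2R), sigma2B2F = as.numeric(fs$sigma2B2F),
      sigma2B2R = as.numeric(fs$sigma2B2R), sigma2F = as.numeric(fs$sigma2F),
      delta = as.numeric(fs$delta), piLambda = as.numeric(fs$piLambda),
      piF = as.numeric(fs$piF), piR = as.numeric(fs$piR), Ywork = fs$Ywork)
}

#' One full Gibbs sweep
#'
#' Runs a single systematic scan over all full conditionals — fixed effects,
#' loadings, loading exclusion probabilities, shrinkage increments, factor
#' scores, factor marker effects and their variances/exclusion
#' probabilities, optional trait-specific marker effects, trait residual
#' variances, and missing-value imputation — and returns the updated state.
#'
#' @param state a \linkS4class{FactorModelState}
#' @param data from [megaModelData()]
#' @param hyper a [megaHyper()] object
#' @return the updated \linkS4class{FactorModelState}
#' @export
gibbsSweep <- function(state, data, hyper) {
  out <- runSampler(state, data, hyper, nIter = 1, burnin = 1, thin = 1,
                    storeU = FALSE, variant = "megabayesc")
  stateFromList(out$finalState, hyper$K, ncol(data$Y))
}

#' Fit the sparse-factor whole-genome regression by MCMC
#'
#' Runs the Gibbs sampler for \code{nIter} sweeps, discarding \code{burnin}
#' and keeping every \code{thin}-th draw thereafter
#' (\code{floor((nIter - burnin)/thin)} stored draws). The
#' \code{"megarrblup"} variant pins every factor-marker exclusion
#' probability to 0 so all markers are included (ridge / RR-BLUP on
#' factors); it is otherwise identical. Focal-trait summaries (total marker
#' effects \code{alphaF = B2F lambda_f}, genetic values, genetic variance)
#' are accumulated per draw and returned on the original trait scale.
#'
#' @inheritParams megaModelData
#' @param nIter,burnin,thin chain settings (\code{burnin < nIter},
#'   \code{thin >= 1})
#' @param seed integer seed or NULL
#' @param variant \code{"megabayesc"} or \code{"megarrblup"}
#' @param storeU keep per-draw genetic-value vectors (needed only for
#'   draw-level prediction intervals; posterior means are always available)
#' @return a \linkS4class{MegaChain}
#' @export
runMcmc <- function(genotypes, phenotypes, hyper, nIter = 10000,
                    burnin = 2000, thin = 2, seed = NULL,
                    variant = c("megabayesc", "megarrblup"), X1 = NULL,
                    X2R = NULL, storeU = TRUE) {
  variant <- match.arg(variant)
  stopIfNot(burnin < nIter, "burnin must be smaller than nIter")
  stopIfNot(thin >= 1, "thin must be >= 1")
  if (variant == "megarrblup") hyper$fixPiF <- 0
  data <- megaModelData(genotypes, phenotypes, hyper, X1 = X1, X2R = X2R)
  withSeed(seed, {
    state <- initializeState(data, hyper, seed = NULL)
    out <- runSampler(state, data, hyper, nIter = nIter, burnin = burnin,
                      thin = thin, storeU = storeU, variant = variant)
    sdF <- data$scale[data$focal]
    draws <- list(
      alphaF = out$alphaF * sdF,
      Lambda = out$Lambda,
      genVar = as.numeric(out$genVar) * sdF^2,
      piF = out$piF, piLambda = out$piLambda, delta = out$delta,
      sigma2R = out$sigma2R * data$scale^2,
      logJoint = as.numeric(out$logJoint))
    if (storeU) draws$u <- out$u * sdF
    postMeans <- list(
      alphaF = stats::setNames(rowMeans(out$alphaF) * sdF, data$markerIds),
      u = stats::setNames(as.numeric(out$uMean) * sdF, rownames(data$X2F)),
      B2F = out$B2FMean, B2R = out$B2RMean,
      Lambda = matrix(rowMeans(out$Lambda), hyper$K, ncol(data$Y)))
    new("MegaChain", draws = draws, posteriorMeans = postMeans,
        settings = list(nIter = nIter, burnin = burnin, thin = thin,
                        seed = if (is.null(seed)) NA_integer_ else seed,
                        variant = variant, K = hyper$K,
                        center = data$center, scale = data$scale),
        markerIds = if (is.null(data$markerIds)) character(0) else data$markerIds,
        traitIds = if (is.null(data$traitIds)) character(0) else data$traitIds,
        focal = as.integer(data$focal),
        finalState = stateFromList(out$finalState, hyper$K, ncol(data$Y)))
  })
}
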