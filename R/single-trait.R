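#' Univariate BayesC regression (ST-BayesC)
#'
#' \code{y = mu + X b + e} with the BayesC mixture prior on every marker
#' effect (shared slab variance, sampled exclusion probability), fit by the
#' same spike-and-slab Gibbs kernel as the factor model. Samples with a
#' missing response are dropped.
#'
#' @param y response vector (focal trait); NA allowed (dropped)
#' @param G a \linkS4class{GenotypeMatrix} or dosage matrix (no missing
#'   dosages)
#' @param nIter,burnin,thin chain settings
#' @param seed integer seed or NULL
#' @param piFix pin the exclusion probability (NULL = sampled, Beta(1,1))
#' @param markerEffectDf,markerEffectScale scaled-Inv-chi-square prior on the
#'   slab variance (scale NULL = data-matched, as in [megaHyper()])
#' @param aSigma,bSigma Inv-Gamma prior on the residual variance
#' @return list with \code{effects} (posterior-mean marker effects, named),
#'   \code{pi}, \code{sigma2e}, \code{sigma2b} (posterior means),
#'   \code{draws} (list of raw draws), \code{mu}, and \code{settings}
#' @export
stBayesC <- function(y, G, nIter = 5000, burnin = 1000, thin = 2,
                     seed = NULL, piFix = NULL, markerEffectDf = 4,
                     markerEffectScale = NULL, aSigma = 1, bSigma = 1) {
  X <- if (is(G, "GenotypeMatrix")) dosages(G) else as.matrix(G)
  keep <- !is.na(y)
  y2 <- y[keep]; X2 <- X[keep, , drop = FALSE]
  stopIfNot(length(y2) >= 3, "need at least 3 non-missing responses")
  if (stats::var(y2) == 0) stop("constant response", call. = FALSE)
  pi0 <- if (is.null(piFix)) 0.5 else piFix
  scl <- if (is.null(markerEffectScale)) {
    markerEffectScaleDefault(X2, pi0) * stats::var(y2)
  } else markerEffectScale
  out <- withSeed(seed,
    st_bayesc_cpp(y2, X2, nu = markerEffectDf, scaleB = scl,
                  aSigma = aSigma, bSigma = bSigma, piA = 1, piB = 1,
                  piFix = if (is.null(piFix)) NA_real_ else piFix,
                  nIter = nIter, burnin = burnin, thin = thin))
  eff <- rowMeans(out$b)
  names(eff) <- colnames(X)
  list(effects = eff, pi = mean(out$pi), sigma2e = mean(out$sigma2e),
       sigma2b = mean(out$sigma2b), mu = mean(out$mu),
       draws = out,
       settings = list(nIter = nIter, burnin = burnin, thin = thin,
                       seed = seed))
}

#' Single-marker association scan
#'
#' Per-marker effect, standard error and Wald P-value for the focal trait.
#' \code{mode = "ols"}: least squares with an intercept plus optional
#' covariates. \code{mode = "mlm"}: the same test with a VanRaden-GRM random
#' effect — variance components are estimated once on the null model, the
#' data are rotated into the GRM eigenbasis, and each marker is tested by
#' generalized least squares (an EMMAX-style approximation). Monomorphic
#' markers get estimate 0 and P = 1 by convention. Markers with missing
#' dosages are mean-imputed for the scan.
#'
#' @param y response vector; NA rows dropped
#' @param G a \linkS4class{GenotypeMatrix} or dosage matrix
#' @param covariates optional numeric covariate matrix (no intercept column)
#' @param mode \code{"ols"} or \code{"mlm"}
#' @param varComp optional named vector \code{c(g = , e = )} pinning the
#'   null-model variance components in mlm mode
#' @return data.frame (\code{GwasResult}): marker, chrom, pos, beta, se, p
#' @export
gwasScan <- function(y, G, covariates = NULL, mode = c("ols", "mlm"),
                     varComp = NULL) {
  mode <- match.arg(mode)
  if (is(G, "GenotypeMatrix")) {
    D <- dosages(G)
    if (any(missingMask(G))) {
      mu <- colMeans(D, na.rm = TRUE)
      idx <- which(missingMask(G), arr.ind = TRUE)
      D[idx] <- mu[idx[, 2]]
    }
    mp <- markerMap(G)
  } else {
    D <- as.matrix(G)
    mp <- data.frame(marker = colnames(D), chrom = "1", pos = seq_len(ncol(D)),
                     stringsAsFactors = FALSE)
    if (is.null(mp$marker)) mp$marker <- paste0("m", seq_len(ncol(D)))
  }
  keep <- !is.na(y)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  y <- y[keep]; D <- D[keep, , drop = FALSE]
  n <- length(y)
  stopIfNot(n >= 3, "need at least 3 non-missing samples")
  X <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(covariates)) as.matrix(covariates)[keep, , drop = FALSE])
  if (mode == "mlm") {
    Kg <- vanRadenGRM(GenotypeMatrix(D))
    if (is.null(varComp)) {
      fit0 <- gblupFit(y, Kg, X = X)
      varComp <- c(g = unname(fit0$varComp[1]), e = unname(fit0$varComp["e"]))
    }
    eg <- eigen(Kg, symmetric = TRUE)
    w <- 1 / sqrt(pmax(varComp["g"] * eg$values + varComp["e"], 1e-12))
    rot <- t(eg$vectors) * w   # rows scaled
    y <- drop(rot %*% y)
    X <- rot %*% X
    D <- rot %*% D
    n <- length(y)
  }
  qrX <- qr(X)
  Q <- qr.Q(qrX)
  yt <- y - Q %*% crossprod(Q, y)
  Dt <- D - Q %*% crossprod(Q, D)
  xtx <- colSums(Dt^2)
  xty <- drop(crossprod(Dt, yt))
  yty <- sum(yt^2)
  df <- n - ncol(X) - 1
  stopIfNot(df >= 1, "not enough residual degrees of freedom")
  mono <- xtx < 1e-10
  beta <- ifelse(mono, 0, xty / xtx)
  sse <- pmax(yty - beta^2 * xtx, 0)
  sigma2 <- sse / df
  se <- ifelse(mono, NA_real_, sqrt(sigma2 / xtx))
  tstat <- ifelse(mono, 0, beta / se)
  p <- ifelse(mono, 1, 2 * stats::pt(-abs(tstat), df))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  data.frame(marker = mp$marker, chrom = mp$chrom, pos = mp$pos,
             beta = beta, se = se, p = p, stringsAsFactors = FALSE)
}
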