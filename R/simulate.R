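#' Simulate independent genotypes
#'
#' Dosages are drawn i.i.d. uniformly from \{0, 1, 2\} (no missing data, no
#' linkage), the genotype distribution used for the factor-scenario study.
#' Markers are placed on chromosome "1" at positions \code{1..p}.
#'
#' @param n samples (default 3000)
#' @param p markers (default 2000)
#' @param seed integer seed, or NULL to use the current RNG stream
#' @return a \linkS4class{GenotypeMatrix}
#' @export
simIndependentGenotypes <- function(n = 3000, p = 2000, seed = NULL) {
  stopIfNot(n >= 1 && p >= 1, "n and p must be >= 1")
  withSeed(seed, {
    d <- matrix(sample(0:2, n * p, replace = TRUE), n, p)
    GenotypeMatrix(d)
  })
}

#' True loading pattern for the factor-scenario simulations
#'
#' \code{t = nfactor * ntraitPerFactor} traits. Trait 1 is the focal trait and
#' loads 1 on every factor (the first column of the loading matrix is all
#' ones). Factor 1 additionally loads 1 on its block of
#' \code{ntraitPerFactor - 1} dedicated secondary traits; each later factor
#' loads 1 on a block of \code{ntraitPerFactor} dedicated secondary traits.
#' All other entries are 0, so factor 1 touches \code{ntraitPerFactor} traits
#' and every later factor \code{ntraitPerFactor + 1}.
#'
#' @param nfactor number of latent factors
#' @param ntraitPerFactor traits per factor
#' @return a \code{nfactor x t} 0/1 matrix
#' @export
buildLambda <- function(nfactor, ntraitPerFactor) {
  stopIfNot(nfactor >= 1 && ntraitPerFactor >= 1,
            "nfactor and ntraitPerFactor must be >= 1")
  t <- nfactor * ntraitPerFactor
  L <- matrix(0, nfactor, t)
  L[, 1] <- 1
  nxt <- 2L
  for (k in seq_len(nfactor)) {
    nsec <- if (k == 1L) ntraitPerFactor - 1L else ntraitPerFactor
    if (nsec > 0) {
      L[k, seq.int(nxt, length.out = nsec)] <- 1
      nxt <- nxt + nsec
    }
  }
  L
}

#' Simulate factor-structured phenotypes on independent genotypes
#'
#' Two genetic architectures. Scenario 1: every factor is controlled by
#' \code{nqtlPerFactor} QTL explaining a fraction \code{factorH2} (default
#' 0.95) of that factor's variance, the rest being Gaussian factor residual.
#' Scenario 2: only factor 1 has QTL (again at \code{factorH2}); the
#' remaining factors are pure Gaussian noise with the same total variance as
#' factor 1, so every factor contributes equally to the focal trait. QTL are
#' drawn without replacement within a factor but independently across factors,
#' so a marker can serve several factors. QTL effects all have magnitude
#' \code{qtlEffect} (default 0.1) with random signs. Each observed trait
#' finally receives trait-specific Gaussian noise equal to \code{traitNoise}
#' (default 10\%) of its total variance. Variance bookkeeping treats the
#' realized genotypes as fixed, so the recorded shares are exact given X.
#'
#' @param G a \linkS4class{GenotypeMatrix} (typically from
#'   [simIndependentGenotypes()])
#' @param config list with \code{scenario} (1 or 2), \code{nfactor},
#'   \code{ntraitPerFactor}, \code{nqtlPerFactor}, optional \code{seed},
#'   \code{factorH2} (0.95), \code{qtlEffect} (0.1), \code{traitNoise} (0.1)
#' @return list with \code{phenotypes} (a \linkS4class{PhenotypeBlock}, trait
#'   1 focal) and \code{truth} (see Details)
#' @details \code{truth} is a list: \code{qtl} (data.frame: marker, factor,
#'   effect, alphaFocal — effect of the draw on the focal trait),
#'   \code{alphaF} (p-vector of summed true marker effects on the focal
#'   trait), \code{Lambda}, per-factor \code{varFG}/\code{varFE}, per-trait
#'   variance decomposition (\code{traitVar}, \code{traitGeneticShare}), and
#'   the focal-trait genetic share \code{focalGeneticShare}.
#' @export
simFactorScenario <- function(G, config) {
  cf <- config
  stopIfNot(all(c("scenario", "nfactor", "ntraitPerFactor", "nqtlPerFactor")
                %in% names(cf)), "config incomplete")
  stopIfNot(cf$scenario %in% c(1, 2), "scenario must be 1 or 2")
  fh2 <- if (is.null(cf$factorH2)) 0.95 else cf$factorH2
  beta0 <- if (is.null(cf$qtlEffect)) 0.1 else cf$qtlEffect
  tn <- if (is.null(cf$traitNoise)) 0.1 else cf$traitNoise
  X <- dosages(G)
  n <- nrow(X); p <- ncol(X)
  stopIfNot(cf$nqtlPerFactor <= p, "nqtlPerFactor exceeds marker count")
  withSeed(cf$seed, {
    K <- cf$nfactor
    L <- buildLambda(K, cf$ntraitPerFactor)
    t <- ncol(L)
    geneticFactors <- if (cf$scenario == 1) seq_len(K) else 1L
    Fg <- matrix(0, n, K)     # genetic part of factors
    qtl <- NULL
    varFG <- numeric(K)
    for (k in geneticFactors) {
      if (cf$nqtlPerFactor > 0) {
        idx <- sample.int(p, cf$nqtlPerFactor, replace = FALSE)
        eff <- beta0 * sample(c(-1, 1), cf$nqtlPerFactor, replace = TRUE)
        Fg[, k] <- X[, idx, drop = FALSE] %*% eff
        qtl <- rbind(qtl, data.frame(marker = markerIds(G)[idx], index = idx,
                                     factor = k, effect = eff,
                                     stringsAsFactors = FALSE))
        varFG[k] <- stats::var(Fg[, k])
      }
    }
    # factor residuals: genetic factors get (1-fh2)/fh2 of their genetic
    # variance; non-genetic factors (scenario 2) match factor 1's total.
    varFE <- numeric(K)
    varF <- numeric(K)
    for (k in seq_len(K)) {
      if (k %in% geneticFactors && varFG[k] > 0) {
        varFE[k] <- varFG[k] * (1 - fh2) / fh2
      } else if (cf$scenario == 2) {
        vf1 <- if (varFG[1] > 0) varFG[1] / fh2 else 1
        varFE[k] <- vf1
      } else {
        varFE[k] <- 1  # degenerate nqtl=0 extension: unit noise factors
      }
      varF[k] <- varFG[k] + varFE[k]
    }
    if (cf$scenario == 1 && cf$nqtlPerFactor == 0) varF[] <- varFE[] <- 1
    Fm <- Fg + matrix(stats::rnorm(n * K), n, K) %*% diag(sqrt(varFE), K)
    core <- Fm %*% L
    # population (X-fixed) trait variances from independent factors
    traitFactorVar <- as.numeric(colSums(L^2 * varF))
    traitNoiseVar <- traitFactorVar * tn / (1 - tn)
    Y <- core + matrix(stats::rnorm(n * t), n, t) %*% diag(sqrt(traitNoiseVar), t)
    colnames(Y) <- c("focal", paste0("sec", seq_len(t - 1)))
    traitGeneticVar <- as.numeric(colSums(L^2 * varFG))
    traitVar <- traitFactorVar + traitNoiseVar
    alphaF <- numeric(p)
    if (!is.null(qtl)) {
      # loading of each factor on the focal trait is L[k, 1]
      qtl$alphaFocal <- qtl$effect * L[qtl$factor, 1]
      af <- tapply(qtl$alphaFocal, qtl$index, sum)
      alphaF[as.integer(names(af))] <- af
    }
    truth <- list(
      qtl = qtl, alphaF = stats::setNames(alphaF, markerIds(G)), Lambda = L,
      varFG = varFG, varFE = varFE, varF = varF,
      traitVar = traitVar, traitGeneticShare = traitGeneticVar / traitVar,
      traitNoiseVar = traitNoiseVar,
      focalGeneticShare = traitGeneticVar[1] / traitVar[1],
      config = cf)
    list(phenotypes = PhenotypeBlock(Y, focalIndex = 1L,
                                     sampleIds = sampleIds(G)),
         truth = truth)
  })
}

#' Simulate genotypes with linkage disequilibrium
#'
#' Haplotypes follow a first-order Markov chain along a chromosome: adjacent
#' markers share alleles with correlation \code{rho} (so adjacent-marker
#' r-squared is about \code{rho^2}); marker allele frequencies are drawn
#' uniformly from \code{mafRange}. Two haplotypes are summed per individual
#' (Hardy-Weinberg within marker). Positions sit on a uniform 1 kb grid. This
#' is an explicit synthetic stand-in for a real structured population: it
#' reproduces local LD decay and variable allele frequency but no long-range
#' structure or demography.
#'
#' @param n samples
#' @param p markers
#' @param seed integer seed or NULL
#' @param rho adjacent-allele correlation in [0, 1)
#' @param mafRange length-2 numeric, allele-frequency band
#' @return a \linkS4class{GenotypeMatrix}
#' @export
simLdGenotypes <- function(n, p, seed = NULL, rho = 0.7,
                           mafRange = c(0.05, 0.5)) {
  stopIfNot(rho >= 0 && rho < 1, "rho must be in [0, 1)")
  withSeed(seed, {
    f <- stats::runif(p, mafRange[1], mafRange[2])
    hap <- function() {
      H <- matrix(0L, n, p)
      H[, 1] <- stats::rbinom(n, 1L, f[1])
      for (j in 2:p) {
        # copy previous allele w.p. rho if frequencies allow, else resample;
        # conditional frequencies keep marginal freq f_j and corr ~ rho
        keep <- stats::runif(n) < rho
        fresh <- stats::rbinom(n, 1L, f[j])
        prev <- H[, j - 1L]
        # previous allele re-expressed at the new frequency: carriers of the
        # previous minor allele get the new minor allele
        H[, j] <- ifelse(keep, prev, fresh)
      }
      H
    }
    d <- hap() + hap()
    GenotypeMatrix(d, pos = as.integer(seq_len(p) * 1000L))
  })
}

#' Simulate an Arabidopsis-like many-trait architecture
#'
#' On a given genotype panel, markers are LD-pruned (r-squared 0.8, windows of
#' 500 markers sliding by 100) and 20 QTL are drawn from the pruned set so QTL
#' are quasi-independent. Ten latent factors are built, each driven by 2
#' distinct QTL with effect magnitudes from U(3, 5), a random half negated;
#' factors carry no residual (all genetic variance flows through the QTL).
#' The focal trait loads 0.5 on every factor; each factor additionally loads
#' 1 on 20 dedicated secondary traits, giving 201 traits. Trait-specific
#' Gaussian noise sets the focal heritability to \code{h2Focal} (0.6) and
#' every secondary-trait heritability to \code{h2Secondary} (0.8). A subset
#' of samples (fraction 649/1003) carries secondary-trait records; the rest
#' have the focal trait only (their secondary cells are missing).
#'
#' @param G a \linkS4class{GenotypeMatrix} with at least 20 polymorphic
#'   markers surviving pruning
#' @param seed integer seed or NULL
#' @param nQtl,nFactor,nSecPerFactor architecture knobs (defaults 20/10/20)
#' @param h2Focal,h2Secondary heritabilities (defaults 0.6 / 0.8)
#' @param secondaryFraction fraction of samples with secondary records
#'   (default 649/1003)
#' @return list with \code{phenotypes} (\linkS4class{PhenotypeBlock}),
#'   \code{truth} (as in [simFactorScenario()], plus per-QTL explained
#'   shares \code{qtlShare}), and \code{partition} (list \code{focalOnly},
#'   \code{withSecondary} of sample indices)
#' @export
simArabidopsisLike <- function(G, seed = NULL, nQtl = 20, nFactor = 10,
                               nSecPerFactor = 20, h2Focal = 0.6,
                               h2Secondary = 0.8,
                               secondaryFraction = 649 / 1003) {
  stopIfNot(nQtl == 2 * nFactor, "nQtl must be 2 * nFactor (2 QTL per factor)")
  X <- dosages(G)
  n <- nrow(X)
  withSeed(seed, {
    kept <- ldPrune(G, r2Max = 0.8, window = 500, step = 100)
    poly <- kept[colVars(X[, kept, drop = FALSE]) > 0]
    if (length(poly) < nQtl)
      stop("fewer than ", nQtl, " eligible QTL candidates after pruning",
           call. = FALSE)
    qtlIdx <- sort(sample(poly, nQtl))
    eff <- stats::runif(nQtl, 3, 5)
    neg <- sample.int(nQtl, nQtl %/% 2)
    eff[neg] <- -eff[neg]
    fac <- rep(seq_len(nFactor), each = 2)[sample.int(nQtl)]  # 2 distinct QTL per factor
    Fm <- matrix(0, n, nFactor)
    for (k in seq_len(nFactor)) {
      sel <- which(fac == k)
      Fm[, k] <- X[, qtlIdx[sel], drop = FALSE] %*% eff[sel]
    }
    t <- 1L + nFactor * nSecPerFactor
    L <- matrix(0, nFactor, t)
    L[, 1] <- 0.5
    for (k in seq_len(nFactor))
      L[k, 1L + (k - 1L) * nSecPerFactor + seq_len(nSecPerFactor)] <- 1
    core <- Fm %*% L
    varFG <- colVars(Fm)
    gFocal <- as.numeric(Fm %*% L[, 1])
    varGfocal <- stats::var(gFocal)
    noiseVar <- numeric(t)
    noiseVar[1] <- varGfocal * (1 - h2Focal) / h2Focal
    for (j in 2:t) {
      k <- which(L[, j] == 1)
      noiseVar[j] <- varFG[k] * (1 - h2Secondary) / h2Secondary
    }
    Y <- core + matrix(stats::rnorm(n * t), n, t) %*% diag(sqrt(noiseVar), t)
    colnames(Y) <- c("focal", paste0("sec", seq_len(t - 1)))
    nB <- round(n * secondaryFraction)
    withSec <- sort(sample.int(n, nB))
    focalOnly <- setdiff(seq_len(n), withSec)
    Y[focalOnly, -1] <- NA
    alphaFocal <- 0.5 * eff
    qtlShare <- alphaFocal^2 * colVars(X[, qtlIdx, drop = FALSE]) /
      (varGfocal + noiseVar[1])
    alphaF <- numeric(ncol(X))
    alphaF[qtlIdx] <- alphaFocal
    qtl <- data.frame(marker = markerIds(G)[qtlIdx], index = qtlIdx,
                      factor = fac, effect = eff, alphaFocal = alphaFocal,
                      stringsAsFactors = FALSE)
    truth <- list(
      qtl = qtl, alphaF = stats::setNames(alphaF, markerIds(G)), Lambda = L,
      varFG = varFG, varFE = rep(0, nFactor), varF = varFG,
      traitVar = colVars(core) + noiseVar,
      focalGeneticShare = varGfocal / (varGfocal + noiseVar[1]),
      qtlShare = qtlShare, prunedMarkers = kept)
    list(phenotypes = PhenotypeBlock(Y, focalIndex = 1L,
                                     sampleIds = sampleIds(G)),
         truth = truth,
         partition = list(focalOnly = focalOnly, withSecondary = withSec))
  })
}

#' Score estimated focal-trait marker effects against simulation truth
#'
#' Each true QTL is parsed one of three ways: (1) the QTL itself is among the
#' candidate markers — its estimate is compared to the truth directly;
#' (2) the QTL is absent but a candidate in LD with it (r-squared >
#' \code{r2Link}) exists — the best-linked candidate stands proxy and the row
#' is flagged (signed effects are then not directly comparable, but explained
#' variance is); (3) neither — the estimated effect and explained variance
#' are set to 0 for that QTL. Candidate markers that are no QTL and not the
#' chosen proxy of one are scored against a true effect of 0. Two RMSEs are
#' returned: of signed effects and of marker-explained standard deviations
#' (square root of \code{var(alpha * x)}, for unit consistency).
#'
#' @param truth the \code{truth} list of a simulator (needs \code{qtl} with
#'   \code{index} and \code{alphaFocal})
#' @param estimates named numeric vector of estimated focal-trait effects for
#'   the candidate markers (names = marker ids)
#' @param G the \linkS4class{GenotypeMatrix} the analysis ran on
#' @param candidates candidate marker ids (defaults to \code{names(estimates)})
#' @param r2Link LD threshold defining a linked proxy (default 0.4)
#' @return list with \code{table} (per-row scoring), \code{rmseEffect},
#'   \code{rmseExplainedSd}
#' @export
scoreEstimates <- function(truth, estimates, G, candidates = names(estimates),
                           r2Link = 0.4) {
  stopIfNot(!is.null(names(estimates)), "estimates must be named by marker id")
  X <- dosages(G)
  ids <- markerIds(G)
  candIdx <- match(candidates, ids)
  stopIfNot(!anyNA(candIdx), "candidates must be markers of G")
  est <- estimates[candidates]
  qtl <- truth$qtl
  expSd <- function(alpha, idx) sqrt(alpha^2 * stats::var(X[, idx]))
  rows <- list()
  usedProxy <- integer(0)
  for (i in seq_len(nrow(qtl))) {
    qi <- qtl$index[i]
    trueA <- qtl$alphaFocal[i]
    if (qi %in% candIdx) {
      e <- est[[match(qi, candIdx)]]
      rows[[length(rows) + 1]] <- data.frame(
        marker = ids[qi], class = "qtl_selected", trueEffect = trueA,
        estEffect = e, trueExpSd = expSd(trueA, qi), estExpSd = expSd(e, qi),
        stringsAsFactors = FALSE)
    } else {
      r2 <- vapply(candIdx, function(ci) pairwiseR2(G, qi, ci), numeric(1))
      if (length(r2) && max(r2) > r2Link) {
        ci <- candIdx[which.max(r2)]
        e <- est[[match(ci, candIdx)]]
        usedProxy <- c(usedProxy, ci)
        rows[[length(rows) + 1]] <- data.frame(
          marker = ids[qi], class = "qtl_linked", trueEffect = trueA,
          estEffect = e, trueExpSd = expSd(trueA, qi), estExpSd = expSd(e, ci),
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          marker = ids[qi], class = "qtl_missed", trueEffect = trueA,
          estEffect = 0, trueExpSd = expSd(trueA, qi), estExpSd = 0,
          stringsAsFactors = FALSE)
      }
    }
  }
  nullIdx <- setdiff(candIdx, c(qtl$index, usedProxy))
  for (ci in nullIdx) {
    e <- est[[match(ci, candIdx)]]
    rows[[length(rows) + 1]] <- data.frame(
      marker = ids[ci], class = "null", trueEffect = 0, estEffect = e,
      trueExpSd = 0, estExpSd = expSd(e, ci), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  list(table = tab,
       rmseEffect = sqrt(mean((tab$estEffect - tab$trueEffect)^2)),
       rmseExplainedSd = sqrt(mean((tab$estExpSd - tab$trueExpSd)^2)))
}
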