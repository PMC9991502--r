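#' Squared correlation between two markers
#'
#' Squared Pearson correlation of the dosage vectors of markers \code{i} and
#' \code{j}, computed over the samples where both are observed. If either
#' marker is monomorphic (zero variance) the value is defined as 0.
#'
#' @param G a \linkS4class{GenotypeMatrix}
#' @param i,j marker indices or ids
#' @return squared correlation in [0, 1]
#' @export
pairwiseR2 <- function(G, i, j) {
  if (is.character(i)) i <- match(i, markerIds(G))
  if (is.character(j)) j <- match(j, markerIds(G))
  d <- dosages(G)
  xi <- d[, i]; xj <- d[, j]
  ok <- !(missingMask(G)[, i] | missingMask(G)[, j])
  xi <- xi[ok]; xj <- xj[ok]
  if (length(xi) < 2 || stats::var(xi) == 0 || stats::var(xj) == 0) return(0)
  stats::cor(xi, xj)^2
}

#' LD pruning in sliding windows
#'
#' Within windows of \code{window} markers (position-sorted within each
#' chromosome), any pair of retained markers with r-squared above
#' \code{r2Max} loses its lower-MAF member; the window then slides by
#' \code{step} markers. Returned indices preserve the input marker order, and
#' the retained set contains no intra-window pair with r-squared above the
#' threshold.
#'
#' @param G a \linkS4class{GenotypeMatrix}
#' @param r2Max r-squared threshold (default 0.8)
#' @param window window size in markers (default 500)
#' @param step slide in markers (default 100)
#' @return integer vector of retained marker indices (into \code{markerIds(G)})
#' @export
ldPrune <- function(G, r2Max = 0.8, window = 500, step = 100) {
  mp <- markerMap(G)
  maf <- markerMaf(G)
  d <- dosages(G)
  keep <- rep(TRUE, nrow(mp))
  for (chr in unique(mp$chrom)) {
    onChr <- which(mp$chrom == chr)
    onChr <- onChr[order(mp$pos[onChr])]
    nc <- length(onChr)
    starts <- seq.int(1L, max(1L, nc), by = step)
    for (s in starts) {
      w <- onChr[seq.int(s, min(s + window - 1L, nc))]
      w <- w[keep[w]]
      if (length(w) >= 2) {
        R2 <- suppressWarnings(
          stats::cor(d[, w, drop = FALSE],
                     use = "pairwise.complete.obs"))^2
        R2[!is.finite(R2)] <- 0   # monomorphic: defined as 0
        inW <- rep(TRUE, length(w))
        for (a in seq_len(length(w) - 1L)) {
          if (!inW[a]) next
          for (b in seq.int(a + 1L, length(w))) {
            if (!inW[b]) next
            if (R2[a, b] > r2Max) {
              # drop the lower-MAF member; ties drop the later marker
              if (isTRUE(maf[w[a]] < maf[w[b]])) inW[a] <- FALSE
              else inW[b] <- FALSE
              if (!inW[a]) break
            }
          }
        }
        keep[w[!inW]] <- FALSE
      }
      if (s + window - 1L >= nc) break
    }
  }
  which(keep)
}

#' Greedy LD clumping of scan results
#'
#' Markers with P-value above \code{pMax} are discarded; then, repeatedly,
#' the most significant unmasked survivor is taken as a candidate and every
#' marker within \code{windowBp} of it (same chromosome) with r-squared above
#' \code{r2Max} is masked permanently. P-value ties break by genomic position
#' then marker id, so the output is invariant to input order.
#'
#' @param gwas a data.frame as returned by [gwasScan()] (columns
#'   \code{marker}, \code{chrom}, \code{pos}, \code{p})
#' @param G the \linkS4class{GenotypeMatrix} the scan ran on
#' @param pMax P-value ceiling for survivors (default 0.01)
#' @param windowBp masking half-window in bp, i.e. +/- windowBp (default 250000)
#' @param r2Max r-squared above which nearby markers are masked (default 0.5)
#' @return a \code{CandidateSet}: data.frame of the taken markers in
#'   selection order (\code{marker, chrom, pos, p}) with the clumping
#'   parameters in \code{attr(, "params")}
#' @export
clumpSelect <- function(gwas, G, pMax = 0.01, windowBp = 250000, r2Max = 0.5) {
  surv <- gwas[!is.na(gwas$p) & gwas$p <= pMax, , drop = FALSE]
  surv <- surv[order(surv$p, surv$chrom, surv$pos, surv$marker), , drop = FALSE]
  taken <- surv[0, , drop = FALSE]
  masked <- rep(FALSE, nrow(surv))
  gIdx <- match(surv$marker, markerIds(G))
  stopIfNot(!anyNA(gIdx), "scan results contain markers absent from G")
  d <- dosages(G)
  while (any(!masked)) {
    top <- which(!masked)[1]
    taken <- rbind(taken, surv[top, , drop = FALSE])
    masked[top] <- TRUE
    near <- which(!masked & surv$chrom == surv$chrom[top] &
                    abs(surv$pos - surv$pos[top]) <= windowBp)
    if (length(near)) {
      r2 <- suppressWarnings(
        stats::cor(d[, gIdx[top]], d[, gIdx[near], drop = FALSE],
                   use = "pairwise.complete.obs"))^2
      r2[!is.finite(r2)] <- 0
      masked[near[drop(r2) > r2Max]] <- TRUE
    }
  }
  rownames(taken) <- NULL
  attr(taken, "params") <- list(pMax = pMax, windowBp = windowBp, r2Max = r2Max)
  taken
}

#' Two-stage association analysis
#'
#' Stage 1: a single-marker scan of the focal trait on the focal-only sample
#' partition, followed by greedy LD clumping ([clumpSelect()]) to form the
#' candidate set. Stage 2: the chosen Bayesian model fit on the second
#' partition (which carries the secondary traits) restricted to the candidate
#' markers. Markers outside the candidate set have an implicit effect of 0.
#'
#' @param G a \linkS4class{GenotypeMatrix} over all samples
#' @param phenotypes a \linkS4class{PhenotypeBlock} over all samples; the
#'   focal trait is taken from it. Secondary-trait cells may be missing on
#'   the stage-1 partition.
#' @param stage1Samples,stage2Samples disjoint sample index vectors: stage 1
#'   uses focal-trait records only, stage 2 uses focal + secondary records
#' @param method \code{"megabayesc"} or \code{"st_bayesc"}
#' @param pMax,windowBp,r2Max clumping parameters (see [clumpSelect()])
#' @param K factors for MegaBayesC (default 30)
#' @param nIter,burnin,thin chain settings
#' @param seed integer seed
#' @param gwasMode stage-1 scan mode, see [gwasScan()]
#' @param fixedFocalFactor pin the first factor to load only on the focal
#'   trait so candidates can act on it directly (default TRUE)
#' @return list with \code{candidates} (the stage-1 CandidateSet),
#'   \code{effects} (data.frame: marker, estimate, explainedVariance,
#'   proportion, significant over the candidates), \code{gwas} (stage-1
#'   scan), and \code{fit} (the stage-2 chain or ST-BayesC fit)
#' @export
runTwoStage <- function(G, phenotypes, stage1Samples, stage2Samples,
                        method = c("megabayesc", "st_bayesc"),
                        pMax = 0.01, windowBp = 250000, r2Max = 0.5,
                        K = 30, nIter = 5000, burnin = 1000, thin = 4,
                        seed = NULL, gwasMode = "ols",
                        fixedFocalFactor = TRUE) {
  method <- match.arg(method)
  stopIfNot(length(intersect(stage1Samples, stage2Samples)) == 0,
            "stage-1 and stage-2 sample partitions must be disjoint")
  Y <- phenoValues(phenotypes)
  fi <- focalIndex(phenotypes)
  y1 <- Y[stage1Samples, fi]
  G1 <- G[stage1Samples, ]
  gwas <- gwasScan(y1, G1, mode = gwasMode)
  cand <- clumpSelect(gwas, G1, pMax = pMax, windowBp = windowBp, r2Max = r2Max)
  yFocal2 <- Y[stage2Samples, fi]
  totVar <- stats::var(yFocal2, na.rm = TRUE)
  if (nrow(cand) == 0) {
    warning("empty candidate set after clumping: all effects are 0")
    eff <- data.frame(marker = character(0), estimate = numeric(0),
                      explainedVariance = numeric(0), proportion = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
    return(list(candidates = cand, effects = eff, gwas = gwas, fit = NULL))
  }
  G2 <- G[stage2Samples, cand$marker]
  X2 <- dosages(G2)
  if (method == "st_bayesc") {
    fit <- stBayesC(yFocal2, G2, nIter = nIter, burnin = burnin, thin = thin,
                    seed = seed)
    est <- fit$effects
  } else {
    ph2 <- PhenotypeBlock(Y[stage2Samples, , drop = FALSE], focalIndex = fi)
    hyper <- megaHyper(K = K, fixedFocalFactor = fixedFocalFactor,
                       nTraits = ncol(Y))
    fit <- runMcmc(G2, ph2, hyper = hyper, nIter = nIter, burnin = burnin,
                   thin = thin, seed = seed)
    est <- focalMarkerEffects(fit)
  }
  mev <- markerExplainedVariance(est, X2, totalVariance = totVar)
  eff <- data.frame(marker = cand$marker,
                    estimate = as.numeric(est),
                    explainedVariance = mev$variance,
                    proportion = mev$proportion,
                    stringsAsFactors = FALSE)
  eff$significant <- classifySignificant(eff, rule = "explained_variance")$significant
  list(candidates = cand, effects = eff, gwas = gwas, fit = fit)
}

#' Variance explained by a marker on the focal trait
#'
#' The empirical variance across individuals of the marker's contribution
#' \code{alpha * x}; the proportion divides by the total focal-trait
#' variance. Vectorized over markers.
#'
#' @param alpha estimated focal-trait effect(s), one per marker
#' @param x dosage vector (one marker) or n x p dosage matrix matching
#'   \code{alpha}
#' @param totalVariance total variance of the focal trait (for the
#'   proportion); NA proportions if omitted
#' @return list with \code{variance} and \code{proportion}, each per marker
#' @export
markerExplainedVariance <- function(alpha, x, totalVariance = NULL) {
  x <- as.matrix(x)
  stopIfNot(length(alpha) == ncol(x), "one alpha per marker column required")
  v <- as.numeric(alpha)^2 * colVars(x)
  prop <- if (is.null(totalVariance)) rep(NA_real_, length(v)) else v / totalVariance
  list(variance = v, proportion = prop)
}

#' Flag significant markers
#'
#' Strict thresholds: under \code{"explained_variance"}, a marker is
#' significant when its explained proportion of focal-trait variance exceeds
#' 0.1\% (\code{proportion > 0.001}); under \code{"pvalue"} when
#' \code{p < 1e-5}.
#'
#' @param results data.frame with a \code{proportion} or \code{p} column
#' @param rule \code{"explained_variance"} or \code{"pvalue"}
#' @param threshold override the default threshold
#' @return \code{results} with a logical \code{significant} column
#' @export
classifySignificant <- function(results,
                                rule = c("explained_variance", "pvalue"),
                                threshold = NULL) {
  rule <- match.arg(rule)
  if (rule == "explained_variance") {
    stopIfNot("proportion" %in% names(results), "need a 'proportion' column")
    thr <- if (is.null(threshold)) 0.001 else threshold
    results$significant <- !is.na(results$proportion) & results$proportion > thr
  } else {
    stopIfNot("p" %in% names(results), "need a 'p' column")
    thr <- if (is.null(threshold)) 1e-5 else threshold
    results$significant <- !is.na(results$p) & results$p < thr
  }
  results
}

#' Match SNPs to annotated genes
#'
#' A SNP matches a gene when its position lies within
#' \code{[start - windowBp, end + windowBp]} (inclusive) on the same
#' chromosome, i.e. within +/- \code{windowBp} of the gene interval.
#' Significant SNPs without any match count as false positives.
#'
#' @param snps data.frame with \code{marker}, \code{chrom}, \code{pos} and
#'   optionally \code{significant} (defaults to all TRUE)
#' @param genes gene table with \code{gene}, \code{chrom}, \code{start},
#'   \code{end} (see [readGeneTable()])
#' @param windowBp matching window (default 100000)
#' @return list with \code{matches} (per-SNP data.frame: marker, matched,
#'   genes as comma-separated ids) and \code{tally} (truePositives,
#'   falsePositives among significant SNPs)
#' @export
matchSnpsToGenes <- function(snps, genes, windowBp = 100000) {
  if (!"significant" %in% names(snps)) snps$significant <- TRUE
  matched <- logical(nrow(snps))
  hits <- character(nrow(snps))
  for (i in seq_len(nrow(snps))) {
    g <- genes[genes$chrom == snps$chrom[i] &
                 snps$pos[i] >= genes$start - windowBp &
                 snps$pos[i] <= genes$end + windowBp, , drop = FALSE]
    matched[i] <- nrow(g) > 0
    hits[i] <- paste(g$gene, collapse = ",")
  }
  sig <- snps$significant
  list(matches = data.frame(marker = snps$marker, matched = matched,
                            genes = hits, stringsAsFactors = FALSE),
       tally = c(truePositives = sum(matched & sig),
                 falsePositives = sum(!matched & sig)))
}
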