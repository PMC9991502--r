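#' Construct a GenotypeMatrix
#'
#' @param dosages numeric matrix, samples x markers. NA cells are recorded in
#'   the missing mask.
#' @param chrom chromosome label per marker (recycled if length 1). Defaults
#'   to \code{"1"}.
#' @param pos 1-based bp position per marker. Defaults to \code{seq_len(p)}.
#' @param markerIds,sampleIds optional ids; defaults are taken from dimnames
#'   or generated (\code{m1..mp}, \code{s1..sn}).
#' @return a \linkS4class{GenotypeMatrix}
#' @export
GenotypeMatrix <- function(dosages, chrom = NULL, pos = NULL,
                           markerIds = NULL, sampleIds = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  p <- ncol(dosages)
  if (is.null(markerIds)) {
    markerIds <- colnames(dosages)
    if (is.null(markerIds)) markerIds <- paste0("m", seq_len(p))
  }
  if (is.null(sampleIds)) {
    sampleIds <- rownames(dosages)
    if (is.null(sampleIds)) sampleIds <- paste0("s", seq_len(nrow(dosages)))
  }
  dimnames(dosages) <- list(sampleIds, markerIds)
  if (is.null(chrom)) chrom <- rep("1", p)
  if (length(chrom) == 1L) chrom <- rep(chrom, p)
  if (is.null(pos)) pos <- seq_len(p)
  map <- data.frame(marker = as.character(markerIds),
                    chrom = as.character(chrom),
                    pos = as.integer(pos), stringsAsFactors = FALSE)
  msk <- is.na(dosages)
  new("GenotypeMatrix", dosages = dosages, map = map, missingMask = msk)
}

#' Construct a PhenotypeBlock
#'
#' @param values numeric matrix, samples x traits; NA cells are missing.
#' @param focalIndex column index (or trait id) of the focal trait.
#' @param traitIds,sampleIds optional ids.
#' @return a \linkS4class{PhenotypeBlock}
#' @export
PhenotypeBlock <- function(values, focalIndex = 1L,
                           traitIds = NULL, sampleIds = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(traitIds)) {
    traitIds <- colnames(values)
    if (is.null(traitIds)) traitIds <- paste0("trait", seq_len(ncol(values)))
  }
  if (is.null(sampleIds)) {
    sampleIds <- rownames(values)
    if (is.null(sampleIds)) sampleIds <- paste0("s", seq_len(nrow(values)))
  }
  dimnames(values) <- list(sampleIds, traitIds)
  if (is.character(focalIndex)) focalIndex <- match(focalIndex, traitIds)
  new("PhenotypeBlock", values = values, focalIndex = as.integer(focalIndex),
      missingMask = is.na(values))
}

#' @rdname GenotypeMatrix-class
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("markerMap", "GenotypeMatrix", function(x) x@map)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("missingMask", "GenotypeMatrix", function(x) x@missingMask)

#' @rdname PhenotypeBlock-class
#' @export
setMethod("missingMask", "PhenotypeBlock", function(x) x@missingMask)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@dosages))

#' @rdname PhenotypeBlock-class
#' @export
setMethod("sampleIds", "PhenotypeBlock", function(x) rownames(x@values))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("markerIds", "GenotypeMatrix", function(x) colnames(x@dosages))

#' @rdname PhenotypeBlock-class
#' @export
setMethod("phenoValues", "PhenotypeBlock", function(x) x@values)

#' @rdname PhenotypeBlock-class
#' @export
setMethod("focalIndex", "PhenotypeBlock", function(x) x@focalIndex)

#' @rdname PhenotypeBlock-class
#' @export
setMethod("traitIds", "PhenotypeBlock", function(x) colnames(x@values))

#' @rdname GenotypeMatrix-class
#' @param i,j,drop subsetting arguments (samples, markers)
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@dosages))
  if (missing(j)) j <- seq_len(ncol(x@dosages))
  if (is.character(j)) j <- match(j, colnames(x@dosages))
  new("GenotypeMatrix",
      dosages = x@dosages[i, j, drop = FALSE],
      map = x@map[j, , drop = FALSE],
      missingMask = x@missingMask[i, j, drop = FALSE])
})

setMethod("show", "GenotypeMatrix", function(object) {
  d <- object@dosages
  cat(sprintf("GenotypeMatrix: %d samples x %d markers\n", nrow(d), ncol(d)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(object@map$chrom), collapse = ", ")))
  cat(sprintf("  missing dosages: %.2f%%\n", 100 * mean(object@missingMask)))
})

setMethod("show", "PhenotypeBlock", function(object) {
  v <- object@values
  cat(sprintf("PhenotypeBlock: %d samples x %d traits (focal: %s)\n",
              nrow(v), ncol(v), colnames(v)[object@focalIndex]))
  cat(sprintf("  missing values: %.2f%%\n", 100 * mean(object@missingMask)))
})

#' @rdname MegaChain-class
#' @export
setMethod("nDraws", "MegaChain", function(x) length(x@draws$genVar))

#' @rdname MegaChain-class
#' @param what name of a stored draw component, e.g. \code{"alphaF"},
#'   \code{"Lambda"}, \code{"genVar"}, \code{"piF"}, \code{"piLambda"},
#'   \code{"sigma2R"}, \code{"delta"}, \code{"u"}, \code{"logJoint"}
#' @export
setMethod("chainDraws", "MegaChain", function(x, what) {
  if (!what %in% names(x@draws)) stop("no stored draws for '", what, "'")
  x@draws[[what]]
})

setMethod("show", "MegaChain", function(object) {
  s <- object@settings
  cat(sprintf("MegaChain (%s): K=%d, %d markers, %d traits\n",
              s$variant, s$K, length(object@markerIds), length(object@traitIds)))
  cat(sprintf("  %d iterations (burnin %d, thin %d) -> %d stored draws\n",
              s$nIter, s$burnin, s$thin, nDraws(object)))
  gv <- object@draws$genVar
  if (length(gv))
    cat(sprintf("  posterior mean genetic variance of focal trait: %.4g\n", mean(gv)))
})
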