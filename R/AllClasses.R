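#' @import methods
NULL

#' Genotype dosage matrix with marker map
#'
#' Samples x markers dosage table (0/1/2, possibly fractional after
#' imputation) together with a marker map (chromosome, 1-based bp position)
#' and a missingness mask. Sample ids are the rownames of \code{dosages},
#' marker ids the colnames (mirrored in \code{map$marker}).
#'
#' @slot dosages numeric matrix, n samples x p markers; observed values in [0, 2].
#' @slot map data.frame with columns \code{marker}, \code{chrom}, \code{pos}.
#' @slot missingMask logical matrix, same dimension as \code{dosages};
#'   \code{TRUE} marks a missing dosage (the corresponding dosage cell is NA).
#'
#' @seealso [GenotypeMatrix()] for the constructor, [filterMarkers()],
#'   [readGenotypeTable()]
#' @export
setClass("GenotypeMatrix",
  slots = c(dosages = "matrix", map = "data.frame", missingMask = "matrix")
)

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosages
  m <- object@map
  msk <- object@missingMask
  msgs <- character()
  if (!is.numeric(d)) msgs <- c(msgs, "dosages must be numeric")
  if (!identical(dim(d), dim(msk))) msgs <- c(msgs, "missingMask dimension mismatch")
  if (!all(c("marker", "chrom", "pos") %in% names(m)))
    msgs <- c(msgs, "map must have columns marker, chrom, pos")
  if (nrow(m) != ncol(d)) msgs <- c(msgs, "map rows must match marker count")
  if (is.null(colnames(d)) || anyDuplicated(colnames(d)))
    msgs <- c(msgs, "marker ids (colnames) must be present and unique")
  if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
    msgs <- c(msgs, "sample ids (rownames) must be present and unique")
  if (nrow(m) > 0 && !identical(as.character(m$marker), colnames(d)))
    msgs <- c(msgs, "map$marker must equal colnames(dosages)")
  if (nrow(m) > 0 && any(m$pos < 1, na.rm = TRUE))
    msgs <- c(msgs, "positions must be >= 1 (1-based bp)")
  obs <- d[!msk]
  if (length(obs) && (anyNA(obs) || any(obs < 0 | obs > 2)))
    msgs <- c(msgs, "observed dosages must be finite and in [0, 2]")
  if (any(is.na(d) & !msk)) msgs <- c(msgs, "NA dosage outside missing mask")
  if (length(msgs)) msgs else TRUE
})

#' Phenotype block: samples x traits with a designated focal trait
#'
#' @slot values numeric matrix, n samples x t traits; rownames are sample ids,
#'   colnames trait ids.
#' @slot focalIndex integer column index of the focal trait.
#' @slot missingMask logical matrix marking missing phenotype cells.
#'
#' @seealso [PhenotypeBlock()] for the constructor
#' @export
setClass("PhenotypeBlock",
  slots = c(values = "matrix", focalIndex = "integer", missingMask = "matrix")
)

setValidity("PhenotypeBlock", function(object) {
  v <- object@values
  msk <- object@missingMask
  msgs <- character()
  if (!is.numeric(v)) msgs <- c(msgs, "values must be numeric")
  if (!identical(dim(v), dim(msk))) msgs <- c(msgs, "missingMask dimension mismatch")
  fi <- object@focalIndex
  if (length(fi) != 1L || is.na(fi) || fi < 1L || fi > ncol(v))
    msgs <- c(msgs, "focalIndex out of range")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msgs <- c(msgs, "trait ids (colnames) must be present and unique")
  if (any(is.na(v) & !msk)) msgs <- c(msgs, "NA value outside missing mask")
  obs <- v[!msk]
  if (length(obs) && any(!is.finite(obs)))
    msgs <- c(msgs, "observed values must be finite")
  if (length(msgs)) msgs else TRUE
})

#' One Gibbs-sampler state of the sparse-factor model
#'
#' Mutable snapshot of every model unknown: factor scores \code{F}, loadings
#' \code{Lambda} with inclusion indicators, fixed-effect coefficients
#' \code{B1}, factor marker effects \code{B2F} (and optional trait-specific
#' marker effects \code{B2R}) with indicators, variance parameters, the
#' multiplicative-shrinkage chain \code{delta} (with \code{tau = cumprod(delta)},
#' \code{delta[1] = 1}), exclusion probabilities, and the working copy of the
#' (partially imputed) trait matrix.
#'
#' @export
setClass("FactorModelState",
  slots = c(
    F = "matrix", Lambda = "matrix", LambdaInd = "matrix",
    B1 = "matrix", B2F = "matrix", B2FInd = "matrix",
    B2R = "matrix", B2RInd = "matrix",
    sigma2R = "numeric", sigma2B2F = "numeric", sigma2B2R = "numeric",
    sigma2F = "numeric", delta = "numeric",
    piLambda = "numeric", piF = "numeric", piR = "numeric",
    Ywork = "matrix"
  )
)

setValidity("FactorModelState", function(object) {
  msgs <- character()
  K <- ncol(object@F)
  if (nrow(object@Lambda) != K) msgs <- c(msgs, "Lambda rows must equal K")
  if (length(object@delta) != K) msgs <- c(msgs, "delta length must equal K")
  if (K > 0 && abs(object@delta[1] - 1) > 1e-12) msgs <- c(msgs, "delta[1] must be 1")
  if (any(object@delta <= 0)) msgs <- c(msgs, "delta must be positive")
  if (!all(object@LambdaInd %in% c(0, 1))) msgs <- c(msgs, "indicators must be 0/1")
  if (any(object@Lambda[object@LambdaInd == 0] != 0))
    msgs <- c(msgs, "excluded loadings must be exactly zero")
  if (any(object@B2F[object@B2FInd == 0] != 0))
    msgs <- c(msgs, "excluded marker effects must be exactly zero")
  if (any(c(object@sigma2R, object@sigma2F) <= 0))
    msgs <- c(msgs, "variances must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Thinned posterior draws of the sparse-factor model
#'
#' Holds post-burn-in, thinned draws of the quantities needed for inference
#' on the focal trait: total marker effects \code{alphaF = B2F \%*\% lambda_f}
#' (computed per draw), genetic values \code{u = X2F \%*\% alphaF}, the
#' empirical genetic variance of the focal trait per draw, loadings, exclusion
#' probabilities and residual variances, plus the per-iteration log joint and
#' chain metadata. Draw count is \code{floor((nIter - burnin) / thin)}.
#'
#' @seealso [runMcmc()], [focalMarkerEffects()], [predictGeneticValues()],
#'   [geneticVarianceSamples()]
#' @export
setClass("MegaChain",
  slots = c(
    draws = "list", posteriorMeans = "list", settings = "list",
    markerIds = "character", traitIds = "character", focal = "integer",
    finalState = "FactorModelState"
  )
)

setValidity("MegaChain", function(object) {
  s <- object@settings
  need <- c("nIter", "burnin", "thin", "seed", "variant", "K")
  if (!all(need %in% names(s))) return("settings incomplete")
  d <- floor((s$nIter - s$burnin) / s$thin)
  if (!is.null(object@draws$genVar) && length(object@draws$genVar) != d)
    return("stored draw count must be floor((nIter - burnin)/thin)")
  TRUE
})
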