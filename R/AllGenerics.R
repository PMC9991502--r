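#' @rdname GenotypeMatrix-class
#' @param object,x a \code{GenotypeMatrix}, \code{PhenotypeBlock} or
#'   \code{MegaChain}
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname PhenotypeBlock-class
#' @export
setGeneric("phenoValues", function(x) standardGeneric("phenoValues"))

#' @rdname PhenotypeBlock-class
#' @export
setGeneric("focalIndex", function(x) standardGeneric("focalIndex"))

#' @rdname PhenotypeBlock-class
#' @export
setGeneric("traitIds", function(x) standardGeneric("traitIds"))

#' @rdname MegaChain-class
#' @export
setGeneric("nDraws", function(x) standardGeneric("nDraws"))

#' @rdname MegaChain-class
#' @export
setGeneric("chainDraws", function(x, what) standardGeneric("chainDraws"))
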