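# Rank-normalize a matrix of draws (iterations x chains) jointly.
rankNormalize <- function(x) {
  r <- rank(x, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  matrix(z, nrow(x), ncol(x))
}

# Classic split-free R-hat on an iterations x chains matrix.
basicRhat <- function(x) {
  n <- nrow(x); m <- ncol(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(colMeans(x))
  if (!is.finite(W) || W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Rank-normalized split R-hat
#'
#' Each chain is split in half (an odd leading draw is dropped), all draws
#' are jointly rank-normalized, and the classical potential-scale-reduction
#' factor is computed; the same is done on the draws folded around their
#' median (to catch scale disagreement), and the larger of the two values is
#' returned. Constant chains give exactly 1 by convention. Invariant to
#' monotone (in particular affine) transformation of the functional.
#'
#' @param bundle draws of one scalar functional: an iterations x chains
#'   matrix, a list of equal-length numeric vectors, or a list of
#'   \linkS4class{MegaChain} objects (their genetic-variance draws are used)
#' @return the R-hat value (>= 1 up to Monte-Carlo error)
#' @export
splitRhat <- function(bundle) {
  if (is.list(bundle) && length(bundle) && is(bundle[[1]], "MegaChain"))
    bundle <- lapply(bundle, function(ch) ch@draws$genVar)
  if (is.list(bundle)) {
    len <- unique(vapply(bundle, length, integer(1)))
    stopIfNot(length(len) == 1, "chains must have equal draw counts")
    bundle <- do.call(cbind, bundle)
  }
  x <- as.matrix(bundle)
  stopIfNot(ncol(x) >= 2, "need at least 2 chains")
  stopIfNot(nrow(x) >= 4, "need at least 4 draws per chain")
  half <- nrow(x) %/% 2
  x <- x[(nrow(x) - 2 * half + 1):nrow(x), , drop = FALSE]
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[half + seq_len(half), , drop = FALSE])
  if (stats::var(as.numeric(xs)) == 0) return(1)
  rBulk <- basicRhat(rankNormalize(xs))
  folded <- abs(xs - stats::median(xs))
  rTail <- if (stats::var(as.numeric(folded)) == 0) 1
           else basicRhat(rankNormalize(folded))
  max(rBulk, rTail)
}

#' Check that the trailing loading rows have shrunk away
#'
#' The multiplicative shrinkage prior pushes rows of the loading matrix
#' beyond the needed rank toward zero; if the last rows still carry sizable
#' loadings, the chosen number of factors K was too small and the chain
#' should be re-run with a larger K.
#'
#' @param chain a \linkS4class{MegaChain}, or a (K*t) x draws matrix of
#'   loading draws with \code{K} supplied
#' @param nTail number of trailing rows to inspect (default 5)
#' @param tol loading magnitude below which a row counts as shrunk;
#'   default = 5\% of the largest posterior-mean absolute loading
#' @param K factor count (needed only for a raw draw matrix)
#' @return list with \code{pass}, \code{perRowMax} (posterior-mean absolute
#'   loading maxima per row), \code{tol}, \code{recommendation}
#' @export
factorTailCheck <- function(chain, nTail = 5, tol = NULL, K = NULL) {
  if (is(chain, "MegaChain")) {
    K <- chain@settings$K
    L <- chain@draws$Lambda
  } else L <- as.matrix(chain)
  stopIfNot(!is.null(K) && K >= 1, "K must be known and >= 1")
  t <- nrow(L) / K
  meanAbs <- matrix(rowMeans(abs(L)), K, t)
  if (K <= nTail) {
    warning("K <= nTail: comparing all ", K, " rows")
    nTail <- K
  }
  if (is.null(tol)) tol <- 0.05 * max(meanAbs)
  perRowMax <- apply(meanAbs, 1, max)
  tailRows <- seq.int(K - nTail + 1, K)
  pass <- all(perRowMax[tailRows] < tol)
  list(pass = pass, perRowMax = perRowMax, tol = tol,
       recommendation = if (pass) {
         "tail loading rows are negligible: K is large enough"
       } else {
         "tail loading rows carry signal: re-run the chain with a larger K"
       })
}

#' Trace table of the largest loadings per factor
#'
#' For every factor, the \code{perFactor} traits with the largest absolute
#' posterior-mean loading are selected (ties broken by trait index) and
#' their draw sequences returned in long, plot-ready form.
#'
#' @param chain a \linkS4class{MegaChain}
#' @param perFactor traces per factor (capped at the trait count)
#' @return data.frame with columns \code{factor}, \code{trait},
#'   \code{draw}, \code{value}
#' @export
topLoadingTraces <- function(chain, perFactor = 5) {
  K <- chain@settings$K
  L <- chain@draws$Lambda
  t <- nrow(L) / K
  d <- ncol(L)
  meanAbs <- matrix(abs(rowMeans(L)), K, t)
  traits <- chain@traitIds
  if (!length(traits)) traits <- paste0("trait", seq_len(t))
  out <- list()
  for (k in seq_len(K)) {
    sel <- order(-meanAbs[k, ], seq_len(t))[seq_len(min(perFactor, t))]
    for (j in sel) {
      idx <- (j - 1) * K + k   # vectorised K x t, column-major
      out[[length(out) + 1]] <- data.frame(
        factor = k, trait = traits[j], draw = seq_len(d),
        value = L[idx, ], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
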