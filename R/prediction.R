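#' VanRaden genomic relationship matrix
#'
#' \code{K = Z Z' / (2 * sum f_l (1 - f_l))} with \code{Z} the dosage matrix
#' centered by twice the allele frequency \code{f_l = mean(dosage)/2}.
#' Monomorphic markers are excluded with a warning. Requires fully observed
#' (imputed) dosages.
#'
#' @param G a \linkS4class{GenotypeMatrix} or dosage matrix
#' @return n x n symmetric kernel matrix with sample ids as dimnames and
#'   \code{attr(, "kind") = "genomic"}
#' @export
vanRadenGRM <- function(G) {
  X <- if (is(G, "GenotypeMatrix")) dosages(G) else as.matrix(G)
  stopIfNot(!anyNA(X), "dosages must be fully observed; impute first")
  f <- colMeans(X) / 2
  poly <- f > 0 & f < 1
  if (!all(poly)) {
    warning(sum(!poly), " monomorphic marker(s) excluded from the GRM")
    X <- X[, poly, drop = FALSE]
    f <- f[poly]
  }
  stopIfNot(ncol(X) > 0, "no polymorphic markers left")
  Z <- sweep(X, 2, 2 * f)
  K <- tcrossprod(Z) / (2 * sum(f * (1 - f)))
  dimnames(K) <- list(rownames(X), rownames(X))
  attr(K, "kind") <- "genomic"
  K
}

#' Secondary-trait (reflectance) relationship matrix
#'
#' \code{H = S S' / ncol(S)} with \code{S} the column-centered and
#' standardized secondary-trait matrix (e.g. hyperspectral BLUEs);
#' zero-variance columns are dropped. The diagonal averages
#' \code{(cols - 1)/cols}, i.e. approximately 1.
#'
#' @param S samples x bands numeric matrix
#' @return n x n symmetric kernel with \code{attr(, "kind") = "reflectance"}
#' @export
reflectanceKernel <- function(S) {
  S <- as.matrix(S)
  v <- colVars(S)
  if (any(v == 0 | !is.finite(v))) {
    S <- S[, v > 0 & is.finite(v), drop = FALSE]
  }
  stopIfNot(ncol(S) > 0, "no variable columns in S")
  Ss <- scale(S)
  H <- tcrossprod(Ss) / ncol(Ss)
  dimnames(H) <- list(rownames(S), rownames(S))
  attr(H, "kind") <- "reflectance"
  H
}

# REML negative log-likelihood for y[tr] with V = sum(s2[k] K_k) + s2e I.
remlNegLogLik <- function(logS2, y, Ks, X) {
  s2 <- exp(logS2)
  n <- length(y)
  V <- diag(s2[length(s2)], n)
  for (k in seq_along(Ks)) V <- V + s2[k] * Ks[[k]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  chX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chX)) return(1e10)
  beta <- backsolve(chX, forwardsolve(t(chX), crossprod(X, Vi_y)))
  Py <- Vi_y - Vi_X %*% beta
  0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) +
           sum(y * Py))
}

#' GBLUP with one or two kernels
#'
#' Mixed model \code{y = X beta + sum_k u_k + e}, \code{u_k ~ N(0, s2_k
#' K_k)}. Variance components are estimated by REML (bounded quasi-Newton on
#' log variances with restarts), then BLUPs of every sample — including
#' those with a masked response — are computed from the training rows:
#' \code{u_k = s2_k K_k[, train] V^{-1} (y - X beta)}.
#'
#' @param y response with NA marking masked/unobserved samples
#' @param kernels one kernel matrix or a list of up to two (e.g.
#'   [vanRadenGRM()] and [reflectanceKernel()])
#' @param X fixed-effect design (NULL = intercept)
#' @param fixedVarComp optional numeric vector of variance components
#'   \code{c(s2_k1, [s2_k2,] s2_e)} to skip REML (also what makes
#'   identity-kernel toys well-posed)
#' @param nRestarts REML restarts from dispersed starting values
#' @return list with \code{u} (total genetic/kernel BLUP per sample),
#'   \code{uPerKernel}, \code{yHat}, \code{beta}, \code{varComp} (named,
#'   ending in \code{e}), \code{h2} (first kernel's share of total
#'   variance), \code{logLik}
#' @export
gblupFit <- function(y, kernels, X = NULL, fixedVarComp = NULL,
                     nRestarts = 3) {
  if (is.matrix(kernels)) kernels <- list(kernels)
  stopIfNot(length(kernels) >= 1 && length(kernels) <= 2,
            "one or two kernels supported")
  n <- length(y)
  for (Kk in kernels) {
    stopIfNot(nrow(Kk) == n && ncol(Kk) == n, "kernel dimension mismatch")
    stopIfNot(max(abs(Kk - t(Kk))) < 1e-8, "kernel must be symmetric")
  }
  tr <- which(!is.na(y))
  stopIfNot(length(tr) >= 3, "need at least 3 training samples")
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  ytr <- y[tr]; Xtr <- X[tr, , drop = FALSE]
  Ktr <- lapply(kernels, function(Kk) Kk[tr, tr, drop = FALSE])
  nv <- length(kernels) + 1
  if (is.null(fixedVarComp)) {
    vy <- stats::var(ytr)
    best <- NULL
    starts <- list(log(rep(vy / nv, nv)),
                   log(c(rep(vy * 0.05, nv - 1), vy * 0.9)),
                   log(c(rep(vy * 0.8 / (nv - 1), nv - 1), vy * 0.2)))
    for (s in seq_len(min(nRestarts, length(starts)))) {
      op <- tryCatch(
        stats::optim(starts[[s]], remlNegLogLik, y = ytr, Ks = Ktr, X = Xtr,
                     method = "L-BFGS-B", lower = log(vy) - 20,
                     upper = log(vy) + 10),
        error = function(e) NULL)
      if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
    }
    stopIfNot(!is.null(best), "REML optimization failed")
    s2 <- exp(best$par)
    ll <- -best$value
  } else {
    s2 <- fixedVarComp
    stopIfNot(length(s2) == nv, "fixedVarComp must have one entry per kernel plus e")
    ll <- -remlNegLogLik(log(pmax(s2, 1e-12)), ytr, Ktr, Xtr)
  }
  V <- diag(s2[nv], length(tr))
  for (k in seq_along(Ktr)) V <- V + s2[k] * Ktr[[k]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(V + diag(1e-8, nrow(V))), error = function(e) NULL)
    stopIfNot(!is.null(ch), "kernel combination is not positive definite")
  }
  Vi <- chol2inv(ch)
  XtViX <- crossprod(Xtr, Vi %*% Xtr)
  beta <- solve(XtViX, crossprod(Xtr, Vi %*% ytr))
  r <- Vi %*% (ytr - Xtr %*% beta)
  uPer <- lapply(seq_along(kernels), function(k) {
    drop(s2[k] * kernels[[k]][, tr, drop = FALSE] %*% r)
  })
  u <- Reduce(`+`, uPer)
  names(u) <- names(y)
  vc <- stats::setNames(s2, c(paste0("k", seq_along(kernels)), "e"))
  list(u = u, uPerKernel = uPer, yHat = drop(X %*% beta) + u,
       beta = drop(beta), varComp = vc, h2 = s2[1] / sum(s2),
       logLik = ll)
}

#' Cross-validation masking plan
#'
#' \code{reps} independent masks, each hiding \code{round(fraction * n)}
#' samples; reproducible from the seed.
#'
#' @param n sample count
#' @param fraction masked fraction in (0, 1) (default 0.5)
#' @param reps repetitions (default 20)
#' @param seed integer seed or NULL
#' @return list of class \code{"CvPlan"}: \code{masks} (list of index
#'   vectors), \code{n}, \code{fraction}, \code{reps}, \code{seed}
#' @export
makeCvPlan <- function(n, fraction = 0.5, reps = 20, seed = NULL) {
  stopIfNot(fraction > 0 && fraction < 1, "fraction must be in (0, 1)")
  masks <- withSeed(seed, {
    lapply(seq_len(reps), function(i) sort(sample.int(n, round(fraction * n))))
  })
  structure(list(masks = masks, n = n, fraction = fraction, reps = reps,
                 seed = seed), class = "CvPlan")
}

#' Heritability-corrected prediction accuracy
#'
#' When secondary traits of the test individuals stay observed during model
#' fitting, the plain correlation between predicted genetic values and
#' observed phenotypes estimates \code{accuracy * sqrt(h2)}; dividing by the
#' square root of the focal-trait heritability corrects it back to the
#' genetic scale.
#'
#' @param uHatTest predicted genetic values of the test samples
#' @param yTest their observed phenotypes
#' @param h2Focal focal-trait heritability in (0, 1]
#' @return corrected accuracy (scalar)
#' @export
correctedAccuracy <- function(uHatTest, yTest, h2Focal) {
  stopIfNot(h2Focal > 0 && h2Focal <= 1, "h2Focal must be in (0, 1]")
  ok <- !is.na(uHatTest) & !is.na(yTest)
  stopIfNot(sum(ok) >= 3, "need at least 3 paired observations")
  if (stats::sd(uHatTest[ok]) == 0 || stats::sd(yTest[ok]) == 0)
    stop("zero-variance input: accuracy undefined", call. = FALSE)
  stats::cor(uHatTest[ok], yTest[ok]) / sqrt(h2Focal)
}

#' Resampling-adjusted t-statistic for paired CV differences
#'
#' Cross-validation repetitions re-use validation data, so accuracy
#' differences across repetitions are positively correlated and the
#' classical one-sample t-test is anti-conservative. The adjusted statistic
#' inflates the denominator by the test/train size ratio:
#' \code{t = mean(d) / sqrt((1/reps + n2/n1) * var(d))}.
#'
#' @param d per-repetition paired differences (length >= 2)
#' @param n1 training-set size
#' @param n2 testing-set size
#' @return the adjusted t value; \code{+/-Inf} when \code{var(d) = 0} with a
#'   nonzero mean, 0 when \code{d} is identically 0
#' @export
adjustedT <- function(d, n1, n2) {
  reps <- length(d)
  stopIfNot(reps >= 2, "need at least 2 repetitions")
  s2 <- stats::var(d)
  m <- mean(d)
  if (s2 == 0) {
    if (m == 0) return(0)
    return(sign(m) * Inf)
  }
  m / sqrt((1 / reps + n2 / n1) * s2)
}
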