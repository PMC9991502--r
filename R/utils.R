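# Internal helpers.

# Evaluate expr under a temporary RNG state seeded with `seed`; if seed is
# NULL, use (and advance) the current RNG stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Minor allele frequency per marker, missing cells ignored.
# f = mean(dosage)/2 over observed cells; maf = min(f, 1 - f).
markerMaf <- function(G) {
  d <- dosages(G)
  d[missingMask(G)] <- NA
  f <- colMeans(d, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA
  pmin(f, 1 - f, na.rm = FALSE)
}

# Per-marker call rate (fraction of non-missing samples).
markerCallRate <- function(G) 1 - colMeans(missingMask(G))

# Column variances (denominator n - 1), missing as NA.
colVars <- function(x) {
  apply(x, 2L, stats::var, na.rm = TRUE)
}

stopIfNot <- function(cond, ...) if (!cond) stop(..., call. = FALSE)
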