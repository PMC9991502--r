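test_that("pairwise r2 handles identity, orthogonality and hand cases", {
  x <- c(0, 1, 2, 0, 1, 2, 1, 0, 2, 1)
  y <- c(2, 0, 1, 1, 2, 0, 0, 2, 1, 1)
  G <- toyGenotypes(cbind(a = x, b = x, c = 2 - x, d = y))
  expect_identical(pairwiseR2(G, "a", "b"), 1)
  expect_equal(pairwiseR2(G, "a", "c"), 1)   # perfect negative LD
  # hand computation via sums
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  expect_equal(pairwiseR2(G, "a", "d"), sxy^2 / (sxx * syy))
  # monomorphic convention
  G2 <- toyGenotypes(cbind(a = x, z = rep(1, 10)))
  expect_identical(pairwiseR2(G2, "a", "z"), 0)
})

test_that("LD pruning removes duplicates, keeps independents, satisfies its postcondition", {
  G <- simIndependentGenotypes(200, 30, seed = 61)
  expect_identical(ldPrune(G, window = 30, step = 10), 1:30)  # independents stay

  d <- dosages(G)
  d[, 5] <- d[, 4]                     # exact duplicate
  G2 <- toyGenotypes(d)
  kept <- ldPrune(G2, window = 30, step = 10)
  expect_identical(sum(c(4, 5) %in% kept), 1L)

  # 60 correlated markers: brute-force all-pairs check of the postcondition
  GL <- simLdGenotypes(150, 60, seed = 62, rho = 0.85)
  kept2 <- ldPrune(GL, r2Max = 0.8, window = 20, step = 5)
  mp <- markerMap(GL)
  for (w in seq(1, 60, by = 5)) {
    win <- intersect(seq(w, min(w + 19, 60)), kept2)
    if (length(win) < 2) next
    for (a in seq_along(win)[-length(win)]) for (b in seq.int(a + 1, length(win))) {
      expect_lte(pairwiseR2(GL, win[a], win[b]), 0.8)
    }
  }
})

# Independent greedy clumping reference: plain transcription of the rule.
clumpReference <- function(gwas, G, pMax, windowBp, r2Max) {
  s <- gwas[!is.na(gwas$p) & gwas$p <= pMax, ]
  out <- character(0)
  while (nrow(s) > 0) {
    o <- order(s$p, s$chrom, s$pos, s$marker)
    top <- s[o[1], ]
    out <- c(out, top$marker)
    dropIdx <- s$marker == top$marker
    for (i in seq_len(nrow(s))) {
      if (dropIdx[i]) next
      if (s$chrom[i] == top$chrom && abs(s$pos[i] - top$pos) <= windowBp &&
          pairwiseR2(G, top$marker, s$marker[i]) > r2Max) dropIdx[i] <- TRUE
    }
    s <- s[!dropIdx, ]
  }
  out
}

test_that("greedy clumping matches an independent reference and is order-invariant", {
  # all P above the ceiling: empty candidate set is valid
  G0 <- simIndependentGenotypes(50, 5, seed = 63)
  gw0 <- data.frame(marker = markerIds(G0), chrom = "1", pos = 1:5,
                    p = rep(0.5, 5))
  expect_identical(nrow(clumpSelect(gw0, G0, pMax = 0.01)), 0L)

  # two perfectly linked markers 1 kb apart: the stronger survives
  x <- rep(c(0, 1, 2), 20)
  G1 <- GenotypeMatrix(cbind(a = x, b = x), pos = c(1000L, 2000L))
  gw1 <- data.frame(marker = c("a", "b"), chrom = "1", pos = c(1000, 2000),
                    p = c(1e-8, 1e-4))
  sel <- clumpSelect(gw1, G1, pMax = 0.01, windowBp = 250000, r2Max = 0.5)
  expect_identical(sel$marker, "a")

  # 100-marker random instance vs brute-force reference; input order ignored
  GL <- simLdGenotypes(150, 100, seed = 64, rho = 0.8)
  set.seed(65)
  y <- rnorm(150) + 0.5 * dosages(GL)[, 30] - 0.4 * dosages(GL)[, 70]
  gw <- gwasScan(y, GL)
  sel1 <- clumpSelect(gw, GL, pMax = 0.1, windowBp = 20000, r2Max = 0.3)
  ref <- clumpReference(gw, GL, pMax = 0.1, windowBp = 20000, r2Max = 0.3)
  expect_identical(sel1$marker, ref)
  perm <- gw[sample.int(nrow(gw)), ]
  sel2 <- clumpSelect(perm, GL, pMax = 0.1, windowBp = 20000, r2Max = 0.3)
  expect_identical(sel2$marker, sel1$marker)
  # postcondition: no retained pair within the window exceeds r2Max
  if (nrow(sel1) > 1) {
    for (a in seq_len(nrow(sel1) - 1)) for (b in seq.int(a + 1, nrow(sel1))) {
      if (abs(sel1$pos[a] - sel1$pos[b]) <= 20000)
        expect_lte(pairwiseR2(GL, sel1$marker[a], sel1$marker[b]), 0.3)
    }
  }
})

test_that("two-stage pipeline validates partitions and degenerates gracefully", {
  GL <- simLdGenotypes(120, 40, seed = 66, rho = 0.4)
  set.seed(67)
  Y <- cbind(focal = rnorm(120), sec = rnorm(120))
  ph <- PhenotypeBlock(Y, sampleIds = sampleIds(GL))
  expect_error(runTwoStage(GL, ph, 1:60, 50:120, method = "st_bayesc"),
               "disjoint")
  expect_warning(
    out <- runTwoStage(GL, ph, 1:60, 61:120, method = "st_bayesc",
                       pMax = 1e-30, nIter = 200, burnin = 50, seed = 68),
    "empty")
  expect_identical(nrow(out$effects), 0L)
})

test_that("with all markers as candidates stage 2 equals the direct fit", {
  GL <- simLdGenotypes(150, 25, seed = 69, rho = 0.2)
  X <- dosages(GL)
  set.seed(70)
  y <- drop(X[, 10] * 0.8) + rnorm(150)
  ph <- PhenotypeBlock(cbind(focal = y, sec = rnorm(150)),
                       sampleIds = sampleIds(GL))
  out <- runTwoStage(GL, ph, 1:50, 51:150, method = "st_bayesc",
                     pMax = 1, r2Max = 1.5, nIter = 1000, burnin = 200,
                     seed = 71)
  expect_identical(nrow(out$candidates), 25L)   # nothing masked or dropped
  direct <- stBayesC(y[51:150], GL[51:150, out$candidates$marker],
                     nIter = 1000, burnin = 200, thin = 4, seed = 71)
  expect_equal(unname(out$effects$estimate), unname(direct$effects))
})

test_that("marker-explained variance follows the definitional formula", {
  x <- c(0, 1, 2, 1, 0, 2, 1, 1)
  sc <- sqrt(0.5 / var(x))
  mev <- markerExplainedVariance(0.1, cbind(x * sc), totalVariance = 2)
  expect_equal(mev$variance, 0.1^2 * 0.5)  # alpha 0.1, var(x) = 0.5 -> 0.005
  expect_equal(mev$proportion, 0.005 / 2)
  expect_equal(unname(markerExplainedVariance(0, cbind(x))$variance), 0)

  # additivity over independent QTL: sum of parts ~ total genetic variance
  G <- simIndependentGenotypes(2000, 20, seed = 72)
  X <- dosages(G)
  set.seed(73)
  a <- rnorm(20, 0, 0.3)
  g <- drop(X %*% a)
  mev2 <- markerExplainedVariance(a, X)
  expect_equal(sum(mev2$variance), var(g), tolerance = 0.1 * var(g))
})

test_that("significance rules use the printed strict inequalities", {
  res <- data.frame(marker = letters[1:5],
                    proportion = c(0.001, 0.0011, 0.1, 0, NA),
                    p = c(1e-5, 9.9e-6, 0.5, 1e-20, NA))
  ev <- classifySignificant(res, "explained_variance")
  expect_identical(ev$significant, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  pv <- classifySignificant(res, "pvalue")
  expect_identical(pv$significant, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_identical(sum(ev$significant), 2L)
})

test_that("SNP-gene matching uses the inclusive +/-100 kb window", {
  genes <- data.frame(gene = c("g1", "g2"), chrom = c("1", "2"),
                      start = c(500000L, 100000L), end = c(510000L, 120000L))
  snps <- data.frame(marker = c("in", "edge", "out", "wrongChrom"),
                     chrom = c("1", "1", "1", "1"),
                     pos = c(505000L, 610000L, 610001L, 110000L),
                     significant = TRUE)
  m <- matchSnpsToGenes(snps, genes, windowBp = 100000)
  expect_identical(m$matches$matched, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(unname(m$tally["truePositives"]), 2L)
  expect_identical(unname(m$tally["falsePositives"]), 2L)
  # brute-force interval oracle over a random toy
  set.seed(74)
  rs <- data.frame(marker = paste0("s", 1:20), chrom = "3",
                   pos = sample.int(1e6, 20), significant = TRUE)
  rg <- data.frame(gene = paste0("g", 1:3), chrom = "3",
                   start = c(2e5, 5e5, 9e5), end = c(2.5e5, 6e5, 9.1e5))
  mm <- matchSnpsToGenes(rs, rg, windowBp = 50000)
  brute <- sapply(rs$pos, function(pp)
    any(pp >= rg$start - 50000 & pp <= rg$end + 50000))
  expect_identical(mm$matches$matched, brute)
})
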