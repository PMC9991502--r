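test_that("independent genotypes are uniform over {0,1,2} and reproducible", {
  G <- simIndependentGenotypes(800, 500, seed = 91)
  d <- dosages(G)
  expect_identical(dim(d), c(800L, 500L))
  expect_false(any(missingMask(G)))
  for (v in 0:2) expect_lt(abs(mean(d == v) - 1 / 3), 0.02)
  G2 <- simIndependentGenotypes(800, 500, seed = 91)
  expect_identical(dosages(G2), d)
})

test_that("loading pattern: all-ones focal column, dedicated secondary blocks", {
  L <- buildLambda(2, 2)
  expect_equal(L, rbind(c(1, 1, 0, 0), c(1, 0, 1, 1)))
  for (cfg in list(c(3, 2), c(2, 5), c(9, 2), c(6, 20))) {
    Lk <- buildLambda(cfg[1], cfg[2])
    expect_equal(dim(Lk), c(cfg[1], cfg[1] * cfg[2]))
    expect_true(all(Lk[, 1] == 1))
    nz <- rowSums(Lk != 0)
    expect_identical(nz[1], cfg[2])
    if (cfg[1] > 1) expect_true(all(nz[-1] == cfg[2] + 1))
    expect_true(all(colSums(Lk[, -1, drop = FALSE] != 0) == 1))
  }
})

test_that("scenario generator bookkeeping is exact and realized shares track it", {
  G <- simIndependentGenotypes(1500, 400, seed = 92)
  X <- dosages(G)
  for (cf in list(list(scenario = 1, nfactor = 2, ntraitPerFactor = 2,
                       nqtlPerFactor = 10, seed = 93),
                  list(scenario = 2, nfactor = 6, ntraitPerFactor = 2,
                       nqtlPerFactor = 10, seed = 94))) {
    sim <- simFactorScenario(G, cf)
    tr <- sim$truth
    # population (X-fixed) shares: factor h2 exactly 0.95 for genetic factors,
    # trait noise exactly 10% of trait variance
    gf <- if (cf$scenario == 1) seq_len(cf$nfactor) else 1
    expect_equal(tr$varFG[gf] / tr$varF[gf], rep(0.95, length(gf)),
                 tolerance = 1e-12)
    expect_equal(tr$traitNoiseVar / tr$traitVar,
                 rep(0.1, length(tr$traitVar)), tolerance = 1e-12)
    expect_equal(tr$focalGeneticShare,
                 0.95 * 0.9 * length(gf) / cf$nfactor, tolerance = 1e-12)
    # realized shares
    y <- phenoValues(sim$phenotypes)[, 1]
    emp <- var(drop(X %*% tr$alphaF)) / var(y)
    expect_lt(abs(emp - tr$focalGeneticShare), 0.2 * tr$focalGeneticShare)
    # all QTL effects have magnitude 0.1
    expect_true(all(abs(tr$qtl$effect) == 0.1))
  }
  # degenerate no-QTL extension: zero heritability
  s0 <- simFactorScenario(G, list(scenario = 1, nfactor = 2,
                                  ntraitPerFactor = 2, nqtlPerFactor = 0,
                                  seed = 95))
  expect_identical(s0$truth$focalGeneticShare, 0)
  expect_error(simFactorScenario(G, list(scenario = 1, nfactor = 2,
                                         ntraitPerFactor = 2,
                                         nqtlPerFactor = 1e6)),
               "exceeds")
})

test_that("LD genotype simulator hits its correlation and frequency targets", {
  G0 <- simLdGenotypes(2000, 100, seed = 96, rho = 0)
  r0 <- sapply(1:99, function(j) pairwiseR2(G0, j, j + 1))
  expect_lt(mean(r0), 0.01)
  G9 <- simLdGenotypes(2000, 100, seed = 97, rho = 0.9)
  r9 <- sapply(1:99, function(j) pairwiseR2(G9, j, j + 1))
  expect_lt(abs(mean(r9) - 0.81), 0.05)
  f <- colMeans(dosages(G9)) / 2
  expect_true(all(pmin(f, 1 - f) > 0.02 & pmin(f, 1 - f) <= 0.52))
  expect_identical(dosages(simLdGenotypes(50, 20, seed = 98)),
                   dosages(simLdGenotypes(50, 20, seed = 98)))
})

test_that("Arabidopsis-like generator: 201 traits, h2 0.6/0.8, partition", {
  G <- simLdGenotypes(600, 300, seed = 99, rho = 0.5, mafRange = c(0.1, 0.5))
  ar <- simArabidopsisLike(G, seed = 100)
  Y <- phenoValues(ar$phenotypes)
  expect_identical(ncol(Y), 201L)
  expect_equal(ar$truth$focalGeneticShare, 0.6, tolerance = 1e-12)
  # secondary heritability bookkeeping: var noise = varF/4
  expect_equal(length(ar$partition$withSecondary), round(600 * 649 / 1003))
  expect_identical(sort(c(ar$partition$focalOnly, ar$partition$withSecondary)),
                   1:600)
  # focal-only samples have missing secondary traits
  expect_true(all(is.na(Y[ar$partition$focalOnly, -1])))
  expect_false(anyNA(Y[ar$partition$withSecondary, ]))
  # effects from U(3,5), half negative
  expect_true(all(abs(ar$truth$qtl$effect) >= 3 & abs(ar$truth$qtl$effect) <= 5))
  expect_identical(sum(ar$truth$qtl$effect < 0), 10L)
  # 2 distinct QTL per factor
  expect_true(all(table(ar$truth$qtl$factor) == 2))
  # realized focal share near 0.6
  emp <- var(drop(dosages(G) %*% ar$truth$alphaF)) / var(Y[, 1])
  expect_lt(abs(emp - 0.6), 0.06)
})

test_that("truth-aware scoring applies the three parsing rules", {
  set.seed(101)
  x1 <- rep(c(0, 1, 2, 1), 10)
  x2 <- 2 - x1                # perfect negative LD proxy of x1
  x3 <- rep(c(0, 2, 1, 1), 10)
  x4 <- sample(x3)            # unlinked
  x5 <- rep(c(1, 0, 2, 2), 10)
  G <- toyGenotypes(cbind(q1 = x1, proxy = x2, q2 = x3, far = x4, null = x5))
  truth <- list(qtl = data.frame(marker = c("q1", "q2"), index = c(1L, 3L),
                                 factor = 1:2, effect = c(0.5, -0.4),
                                 alphaFocal = c(0.5, -0.4)))
  # perfect estimates, all QTL in candidates: both RMSEs 0
  est <- c(q1 = 0.5, q2 = -0.4)
  sc <- scoreEstimates(truth, est, G)
  expect_equal(sc$rmseEffect, 0)
  expect_equal(sc$rmseExplainedSd, 0)

  # q1 missing, its negative proxy selected: effect error includes the sign
  # flip, explained-sd error stays small; q2 missed entirely -> zero rule
  est2 <- c(proxy = -0.5, null = 0)
  sc2 <- scoreEstimates(truth, est2, G)
  tab <- sc2$table
  expect_identical(tab$class[tab$marker == "q1"], "qtl_linked")
  expect_identical(tab$class[tab$marker == "q2"], "qtl_missed")
  expect_identical(tab$class[tab$marker == "null"], "null")
  expect_equal(tab$estEffect[tab$marker == "q2"], 0)
  # hand computation: rows are (q1: 0.5 vs -0.5), (q2: -0.4 vs 0), (null: 0 vs 0)
  expect_equal(sc2$rmseEffect, sqrt(mean(c(1^2, 0.4^2, 0))))
  sdq1 <- sqrt(0.5^2 * var(x1))
  sdq2 <- sqrt(0.4^2 * var(x3))
  expect_equal(sc2$rmseExplainedSd, sqrt(mean(c(0, sdq2^2, 0))))

  # missed QTL contributes |true effect| through the zero rule
  sc3 <- scoreEstimates(truth, c(null = 0), G)
  expect_equal(sc3$rmseEffect, sqrt(mean(c(0.5^2, 0.4^2, 0))))
})
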