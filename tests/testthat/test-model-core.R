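test_that("spike-slab kernel matches the closed-form two-component posterior", {
  x <- c(1, 0, -1); yr <- c(0.5, 0, -0.5)
  # analytic: v = (x'x/s2e + 1/s2b)^-1, m = v x'y/s2e, BF and inclusion prob
  v <- 1 / (2 + 1); m <- v * 1
  logBF <- 0.5 * log(v / 1) + 0.5 * m^2 / v
  pIncl <- 1 / (1 + exp(-logBF))     # pi = 0.5: prior odds 1
  set.seed(99)
  ind <- replicate(1e5, spikeSlabUpdate(yr, x, 1, 1, 0.5)$indicator)
  mcse <- sqrt(pIncl * (1 - pIncl) / 1e5)
  expect_lt(abs(mean(ind) - pIncl), 3 * mcse)

  # pi = 0: conditional mean equals the ridge solution
  u <- spikeSlabUpdate(yr, x, sigma2E = 1, sigma2B = 2, pi = 0)
  expect_equal(u$mean, sum(x * yr) / (sum(x^2) + 1 / 2), tolerance = 1e-8)
  expect_identical(u$indicator, 1L)

  # pi = 1: forced exclusion, coefficient exactly 0
  u1 <- spikeSlabUpdate(yr, x, 1, 1, 1)
  expect_identical(u1$coefficient, 0)
  expect_identical(u1$indicator, 0L)

  # degenerate zero-variance covariate: indicator follows the prior odds
  set.seed(7)
  pe <- mean(replicate(4000, spikeSlabUpdate(yr, rep(0, 3), 1, 1, 0.7)$indicator))
  expect_lt(abs(pe - 0.3), 3 * sqrt(0.3 * 0.7 / 4000))
})

test_that("initialization is deterministic, validates inputs and pins fixed loadings", {
  G <- simIndependentGenotypes(40, 15, seed = 1)
  Y <- matrix(rnorm(40 * 4), 40, 4)
  Y[, 4] <- NA   # an all-missing trait column must still initialize
  ph <- PhenotypeBlock(Y, sampleIds = sampleIds(G))
  hy <- megaHyper(K = 2, fixedFocalFactor = TRUE, nTraits = 4)
  data <- megaModelData(G, ph, hy)
  s1 <- initializeState(data, hy, seed = 5)
  s2 <- initializeState(data, hy, seed = 5)
  expect_identical(s1@F, s2@F)
  expect_identical(s1@B2FInd, s2@B2FInd)
  expect_equal(unname(s1@Lambda[1, ]), c(1, 0, 0, 0))

  # the pinned row survives sweeping, its indicator pattern matches the values
  set.seed(9)
  st <- s1
  for (i in 1:5) st <- gibbsSweep(st, data, hy)
  expect_equal(unname(st@Lambda[1, ]), c(1, 0, 0, 0))
  expect_true(all(st@Lambda[st@LambdaInd == 0] == 0))
  expect_true(all(st@B2F[st@B2FInd == 0] == 0))

  expect_error(initializeState(data, megaHyper(K = 10), seed = 1),
               "K must not exceed")
  Ybad <- Y; Ybad[1, 1] <- Inf
  expect_error(megaModelData(G, PhenotypeBlock(Ybad, sampleIds = sampleIds(G)),
                             hy), "finite")
})

test_that("chain bookkeeping: draw counts, determinism, finite log joint", {
  G <- simIndependentGenotypes(25, 6, seed = 2)
  Y <- matrix(rnorm(50), 25, 2)
  ph <- PhenotypeBlock(Y, sampleIds = sampleIds(G))
  hy <- megaHyper(K = 1)
  ch <- runMcmc(G, ph, hy, nIter = 10000, burnin = 2000, thin = 2, seed = 3)
  expect_identical(nDraws(ch), 4000L)
  expect_true(all(is.finite(chainDraws(ch, "logJoint"))))

  ch2 <- runMcmc(G, ph, hy, nIter = 10000, burnin = 2000, thin = 2, seed = 3)
  expect_identical(chainDraws(ch, "alphaF"), chainDraws(ch2, "alphaF"))
  expect_identical(chainDraws(ch, "genVar"), chainDraws(ch2, "genVar"))

  # floor rule for uneven thinning
  ch3 <- runMcmc(G, ph, hy, nIter = 105, burnin = 20, thin = 8, seed = 3)
  expect_identical(nDraws(ch3), 10L)   # floor((105 - 20) / 8)
})

test_that("the ridge variant includes every marker", {
  G <- simIndependentGenotypes(30, 8, seed = 4)
  ph <- PhenotypeBlock(matrix(rnorm(30), 30, 1), sampleIds = sampleIds(G))
  ch <- runMcmc(G, ph, megaHyper(K = 1), nIter = 200, burnin = 50, thin = 2,
                seed = 5, variant = "megarrblup")
  expect_true(all(ch@finalState@B2FInd == 1))
  expect_true(all(chainDraws(ch, "piF") == 0))
})

test_that("residual variance conditional centers on its analytic posterior", {
  set.seed(6)
  n <- 10
  Y <- cbind(rnorm(n, 2, 1), rnorm(n, -1, 2))
  ph <- PhenotypeBlock(Y)
  G <- simIndependentGenotypes(n, 3, seed = 7)
  # loadings pinned to zero: the model is an intercept plus noise per trait
  hy <- megaHyper(K = 1, fixedLoadings = matrix(0, 1, 2), scaleY = FALSE)
  ch <- runMcmc(G, ph, hy, nIter = 20000, burnin = 2000, thin = 2, seed = 8)
  s2draws <- chainDraws(ch, "sigma2R")
  # flat intercept integrated out: sigma2 ~ Inv-Gamma(a + (n-1)/2, b + SS/2)
  for (j in 1:2) {
    SS <- sum((Y[, j] - mean(Y[, j]))^2)
    postMean <- (1 + SS / 2) / (1 + (n - 1) / 2 - 1)
    expect_equal(mean(s2draws[j, ]), postMean, tolerance = 0.1)
  }
})

test_that("pinned-factor ridge fit matches the conjugate ridge oracle", {
  set.seed(10)
  n <- 60; p <- 20
  G <- simIndependentGenotypes(n, p, seed = 11)
  X <- dosages(G)
  y <- drop(X %*% rnorm(p, 0, 0.1)) + rnorm(n)
  ph <- PhenotypeBlock(matrix(y, ncol = 1), sampleIds = sampleIds(G))
  vb <- 0.01; veR <- 0.5; veF <- 0.5
  hy <- megaHyper(K = 1, fixedFocalFactor = TRUE, nTraits = 1,
                  fixSigma2B2F = vb, fixSigma2R = veR, fixSigma2F = veF,
                  scaleY = FALSE)
  ch <- runMcmc(G, ph, hy, nIter = 6000, burnin = 1000, thin = 2, seed = 12,
                variant = "megarrblup")
  a <- focalMarkerEffects(ch)
  yc <- y - mean(y)
  ridge <- drop(solve(crossprod(X) + diag((veR + veF) / vb, p),
                      crossprod(X, yc)))
  expect_gt(cor(a, ridge), 0.99)
  expect_lt(max(abs(a - ridge)), 0.25 * sd(ridge) + 0.005)
  # fitted genetic values agree even more tightly
  expect_gt(cor(drop(X %*% a), drop(X %*% ridge)), 0.995)
})

test_that("posterior functionals are per-draw products and linear maps", {
  # 3-draw toy chain: alphaF draws given directly
  a <- cbind(c(1, 0, 2), c(0, 1, -1), c(2, 2, 0))
  X <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  ch <- toyChain(a, X2F = X)
  expect_equal(unname(focalMarkerEffects(ch)), rowMeans(a))
  # one-hot rows return the effect entries themselves
  u <- predictGeneticValues(ch, X)
  expect_equal(unname(u[1:3]), unname(rowMeans(a)))
  expect_equal(unname(u[4]), sum(rowMeans(a)))
  # per-draw variance of genetic values
  gv <- geneticVarianceSamples(ch, X)
  expect_equal(gv, apply(X %*% a, 2, var))
  expect_equal(geneticVarianceSamples(toyChain(matrix(0, 3, 2), X2F = X), X),
               c(0, 0))
  # marker mismatch errors
  expect_error(predictGeneticValues(ch, X[, 1:2]), "mismatch")
})

test_that("cumulative-product shrinkage grows geometrically under its prior", {
  set.seed(13)
  K <- 6; aD <- 2; bD <- 1
  taus <- replicate(4000, cumprod(c(1, rgamma(K - 1, aD, bD))))
  expect_equal(rowMeans(taus), (aD / bD)^(0:(K - 1)), tolerance = 0.15)
  # sampler state stores delta with the same convention
  G <- simIndependentGenotypes(30, 5, seed = 14)
  ph <- PhenotypeBlock(matrix(rnorm(90), 30, 3), sampleIds = sampleIds(G))
  hy <- megaHyper(K = 2)
  st <- initializeState(megaModelData(G, ph, hy), hy, seed = 15)
  expect_identical(st@delta[1], 1)
})
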