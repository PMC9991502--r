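test_that("VanRaden GRM matches a hand computation and its normalization", {
  d <- rbind(c(0, 1, 2, 1), c(2, 1, 0, 1), c(1, 1, 1, 2))
  G <- toyGenotypes(d)
  K <- vanRadenGRM(G)
  # explicit-loop oracle
  f <- colSums(d) / (2 * nrow(d))
  Z <- d - matrix(2 * f, 3, 4, byrow = TRUE)
  denom <- 2 * sum(f * (1 - f))
  Kref <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) Kref[i, j] <- sum(Z[i, ] * Z[j, ]) / denom
  expect_equal(unname(K), Kref, tolerance = 1e-12, ignore_attr = TRUE)

  # identical samples give identical rows and K[i,i] = K[i,j]
  d2 <- rbind(c(0, 2, 1), c(0, 2, 1), c(2, 0, 1))
  K2 <- vanRadenGRM(toyGenotypes(d2))
  expect_equal(K2[1, ], K2[2, ])
  expect_equal(K2[1, 1], K2[1, 2])

  # random-mating (Hardy-Weinberg) panel: mean diagonal ~ 1
  G3 <- simLdGenotypes(500, 600, seed = 81, rho = 0, mafRange = c(0.1, 0.5))
  expect_lt(abs(mean(diag(vanRadenGRM(G3))) - 1), 0.1)

  # monomorphic markers excluded with a warning
  expect_warning(vanRadenGRM(cbind(c(0, 1, 2), c(0, 0, 0))), "monomorphic")
})

test_that("reflectance kernel is the scaled cross-product of standardized bands", {
  s <- matrix(c(1, -1), 2, 1)
  H <- reflectanceKernel(s)
  ss <- scale(s)
  expect_equal(unname(H), unname(tcrossprod(ss) / 1), tolerance = 1e-12,
               ignore_attr = TRUE)

  set.seed(82)
  S <- matrix(rnorm(100 * 40), 100, 40)
  H2 <- reflectanceKernel(S)
  expect_lt(max(abs(H2 - t(H2))), 1e-12)
  expect_equal(mean(diag(H2)), (40 - 1) / 40, tolerance = 0.02)
  # zero-variance band dropped
  expect_equal(dim(reflectanceKernel(cbind(S, 0))), c(100L, 100L))
})

test_that("GBLUP with fixed components matches the ridge-to-the-mean closed form", {
  set.seed(83)
  y <- rnorm(10, 5, 2)
  K <- diag(10)
  fit <- gblupFit(y, K, fixedVarComp = c(2, 1))
  shrink <- 2 / (2 + 1)
  expect_equal(unname(fit$u), shrink * (y - mean(y)), tolerance = 1e-8)
  # zero genetic variance: constant predictions at the mean
  fit0 <- gblupFit(y, K, fixedVarComp = c(0, 1))
  expect_equal(unname(fit0$u), rep(0, 10))
  expect_equal(unname(fit0$yHat), rep(mean(y), 10), tolerance = 1e-8)
})

test_that("single-kernel REML recovers a simulated heritability of 0.5", {
  G <- simLdGenotypes(500, 800, seed = 84, rho = 0.3, mafRange = c(0.1, 0.5))
  X <- dosages(G)
  set.seed(85)
  g <- drop(X %*% rnorm(800)); g <- g / sd(g)
  y <- g + rnorm(500)
  fit <- gblupFit(y, vanRadenGRM(G))
  expect_lt(abs(fit$h2 - 0.5), 0.1)
  # masked samples still get predictions correlated with their true values
  y2 <- y; y2[1:100] <- NA
  fit2 <- gblupFit(y2, vanRadenGRM(G))
  expect_gt(cor(fit2$u[1:100], g[1:100]), 0.3)
})

test_that("two-kernel REML splits variance between informative kernels", {
  set.seed(86)
  n <- 200
  G <- simLdGenotypes(n, 400, seed = 87, rho = 0.2, mafRange = c(0.1, 0.5))
  Kg <- vanRadenGRM(G)
  S <- matrix(rnorm(n * 60), n, 60)
  H <- reflectanceKernel(S)
  g <- drop(dosages(G) %*% rnorm(400)); g <- g / sd(g)
  h <- drop(scale(S) %*% rnorm(60)) / sqrt(60); h <- h / sd(h)
  y <- g + h + rnorm(n, 0, 0.5)
  fit <- gblupFit(y, list(Kg, H))
  vc <- fit$varComp
  expect_gt(vc["k1"], 0.2)
  expect_gt(vc["k2"], 0.2)
  expect_lt(vc["e"], 1.5)
  expect_gt(cor(fit$u, g + h), 0.8)
})

test_that("cross-validation plans are sized, reproducible and covering", {
  plan <- makeCvPlan(1000, fraction = 0.5, reps = 20, seed = 88)
  expect_length(plan$masks, 20)
  expect_true(all(lengths(plan$masks) == 500))
  plan2 <- makeCvPlan(1000, fraction = 0.5, reps = 20, seed = 88)
  expect_identical(plan$masks, plan2$masks)
  # each sample is masked at least once with probability 1 - 2^-20 each;
  # under this seed the union covers everything
  expect_identical(sort(unique(unlist(plan$masks))), 1:1000)
  expect_error(makeCvPlan(10, fraction = 1.2), "fraction")
})

test_that("corrected accuracy rescales by heritability and tracks the truth", {
  y <- rnorm(50)
  expect_equal(correctedAccuracy(y, y, 1), 1)
  u <- rnorm(50)
  expect_equal(correctedAccuracy(2 * u + 3, y, 0.5),
               correctedAccuracy(u, y, 0.5))   # affine invariance
  expect_error(correctedAccuracy(rep(1, 50), y, 0.5), "zero-variance")

  # simulation oracle: y = u + e at h2 = 0.5; corrected estimate ~ cor(uhat, u)
  set.seed(89)
  n <- 2000
  u <- rnorm(n)
  y2 <- u + rnorm(n)
  uhat <- u + rnorm(n, 0, 0.7)
  trueAcc <- cor(uhat, u)
  expect_lt(abs(correctedAccuracy(uhat, y2, 0.5) - trueAcc), 0.05)
})

test_that("adjusted t matches the printed formula and bounds the classical t", {
  expect_identical(adjustedT(rep(0, 6), 100, 100), 0)
  expect_identical(adjustedT(rep(1, 4), 100, 100), Inf)
  d <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_equal(adjustedT(d, 100, 100), sqrt(3), tolerance = 1e-12)
  set.seed(90)
  for (i in 1:10) {
    dd <- rnorm(8, 0.2, 0.3)
    classical <- mean(dd) / sqrt(var(dd) / 8)
    expect_lte(abs(adjustedT(dd, 50, 25)), abs(classical))
  }
})
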