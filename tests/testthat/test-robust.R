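test_that("initialization imputes missing entries by the row mean", {
  # fully observed: Y0 is the data, untouched
  M <- randomMasked(5, 4, seed = 1)
  d0 <- initializeDecomposition(M, solverConfig(rank = 2, seed = 2))
  expect_identical(d0@Y, maskedValues(M))
  expect_true(all(d0@S == 0) && all(d0@Lambda == 0))

  # row observing {2, 4} with entry 3 missing imputes (2+4)/2 = 3
  vals <- matrix(c(2, 1, NA, 1, 4, 1), 2, 3)  # row 1: 2, NA, 4
  d1 <- initializeDecomposition(MaskedMatrix(vals), solverConfig(rank = 1))
  expect_identical(d1@Y[1, 2], 3)

  # a fully missing row falls back to the global observed mean
  vals2 <- rbind(c(NA, NA, NA), c(1, 2, 3))
  expect_warning(
    d2 <- initializeDecomposition(MaskedMatrix(vals2), solverConfig(rank = 1)),
    "global mean")
  expect_identical(unname(d2@Y[1, ]), c(2, 2, 2))

  expect_error(
    initializeDecomposition(MaskedMatrix(matrix(NA_real_, 2, 2)),
                            solverConfig(rank = 1)),
    "no observed")
})

test_that("Y update matches its closed form and the scalar oracle", {
  cfg <- solverConfig(rank = 2, rhoAug = 1)
  vals <- matrix(c(3, 1, 2, NA), 2, 2)
  M <- MaskedMatrix(vals)
  dec <- initializeDecomposition(M, cfg)
  dec@Lambda[1, 1] <- 0.5
  dec@S[1, 1] <- 0.5
  Y <- updateY(dec, M, cfg)
  UVt <- fittedMatrix(dec@factors)

  # unobserved entries take the low-rank fit
  expect_identical(Y[2, 2], UVt[2, 2])

  # frozen scalar case a=1, lam=0.5, rho=1, m=3, s=0.5 -> 2.0, confirmed by
  # golden-section minimization of the per-entry objective
  dec2 <- dec
  dec2@factors@U[] <- 1; dec2@factors@V[] <- 0.5  # (UV^t)_11 = 1
  Y2 <- updateY(dec2, M, cfg)
  expect_equal(Y2[1, 1], 2.0, tolerance = 1e-12)
  expect_equal(scalarMin(yObjective(1, 0.5, 1, 3, 0.5), -10, 10), 2.0,
               tolerance = 1e-6)

  # rho -> infinity drives observed entries to m - s
  cfgBig <- solverConfig(rank = 2, rhoAug = 1e10)
  Ybig <- updateY(dec, M, cfgBig)
  expect_equal(Ybig[1, 1], vals[1, 1] - 0.5, tolerance = 1e-6)
})

test_that("soft threshold is the l1 proximal operator", {
  expect_identical(softThreshold(5, 2), 3)
  expect_identical(softThreshold(-5, 2), -3)
  expect_identical(softThreshold(0.5, 1), 0)
  expect_identical(softThreshold(2, 2), 0)   # closed dead zone at |y| = t
  expect_error(softThreshold(1, -0.1), "non-negative")

  # brute-force minimization of .5(y-x)^2 + t|x| agrees
  for (y in c(-5, -1.3, 0, 0.4, 2.7)) {
    brute <- gridMin(function(x) 0.5 * (y - x)^2 + 2 * abs(x), -10, 10)
    expect_equal(softThreshold(y, 2), brute, tolerance = 1e-3)
  }
})

test_that("S update soft-thresholds the scaled residual on the observed set", {
  vals <- matrix(c(10, 1, 2, NA), 2, 2)
  M <- MaskedMatrix(vals)
  cfg <- solverConfig(rank = 1, rhoAug = 1, lambda = 2)
  dec <- initializeDecomposition(M, cfg)
  dec@Y <- matrix(1, 2, 2)
  S <- updateS(dec, M, cfg)

  # frozen scalar case m=10, y=1, lam=0, rho=1, lambda=2 -> 7, confirmed by
  # the numerical oracle on the per-entry objective
  expect_equal(S[1, 1], 7, tolerance = 1e-12)
  expect_equal(scalarMin(sObjective(2, 0, 1, 10, 1), -20, 20), 7,
               tolerance = 1e-6)

  expect_identical(S[2, 2], 0)               # off the observed set
  expect_identical(S[2, 1], 0)               # dead zone: |1-1| <= 2
})

test_that("Y and S updates agree with per-entry numerical minimization", {
  # random instances spanning the penalty scales
  cases <- expand.grid(rho = c(0.1, 1, 10), lambda = c(0.1, 1, 10))
  for (i in seq_len(nrow(cases))) {
    rho <- cases$rho[i]; lambda <- cases$lambda[i]
    set.seed(100 + i)
    M <- randomMasked(6, 5, seed = 100 + i, missFrac = 0.2)
    cfg <- solverConfig(rank = 2, rhoAug = rho, lambda = lambda,
                        seed = 200 + i)
    dec <- initializeDecomposition(M, cfg)
    dec@Lambda[observedMask(M)] <- rnorm(sum(observedMask(M)))
    dec@S[observedMask(M)] <- rnorm(sum(observedMask(M)))
    dec@Y <- dec@Y + matrix(rnorm(30), 6, 5)

    Y <- updateY(dec, M, cfg)
    S <- updateS(dec, M, cfg)
    UVt <- fittedMatrix(dec@factors)
    obs <- which(observedMask(M), arr.ind = TRUE)
    for (k in sample(nrow(obs), 6)) {
      r <- obs[k, 1]; c <- obs[k, 2]
      yOracle <- scalarMin(
        yObjective(UVt[r, c], dec@Lambda[r, c], rho,
                   maskedValues(M)[r, c], dec@S[r, c]), -60, 60)
      expect_equal(Y[r, c], yOracle, tolerance = 1e-6)
      sOracle <- scalarMin(
        sObjective(lambda, dec@Lambda[r, c], rho,
                   maskedValues(M)[r, c], dec@Y[r, c]), -60, 60)
      expect_equal(S[r, c], sOracle, tolerance = 1e-6)
    }
  }
})

test_that("dual ascent acts only on the observed constraint set", {
  M <- MaskedMatrix(matrix(c(1, 2, NA, 4), 2, 2))
  cfg <- solverConfig(rank = 1, seed = 3)
  dec <- initializeDecomposition(M, cfg)

  # feasible point: M = Y + S on the observed set leaves the dual unchanged
  dec@S <- matrix(0, 2, 2)
  Lam <- updateDual(dec, M)
  expect_identical(Lam, dec@Lambda)

  # a single residual of 0.3 moves only its own multiplier
  dec@Y[1, 1] <- dec@Y[1, 1] - 0.3
  Lam2 <- updateDual(dec, M)
  expect_equal(Lam2[1, 1], 0.3, tolerance = 1e-12)
  expect_identical(Lam2[1, 2], 0)            # off the observed set
  expect_identical(Lam2[2, 1], 0)
})

test_that("ADMM keeps S and Lambda supported on the observed set and factors positive", {
  inst <- injectMissing(
    injectOutliers(makeToy(20, 15, 2, seed = 41), 0.05, seed = 42),
    0.1, seed = 43)
  cfg <- admmConfig(rank = 2, lambda = 1, seed = 4, outerMaxIter = 60)
  dec <- suppressWarnings(robustNMF(inst@M, cfg))
  off <- !observedMask(inst@M)
  expect_true(all(outlierMatrix(dec)[off] == 0))
  expect_true(all(dualMatrix(dec)[off] == 0))
  h <- solverHistory(dec)
  expect_true(all(h$minU > 0) && all(h$minV > 0))
  expect_lte(h$primal[nrow(h)], h$primal[1])

  # step-by-step: the exported updates preserve the support invariant
  d <- initializeDecomposition(inst@M, cfg)
  for (k in 1:5) {
    d@Y <- updateY(d, inst@M, cfg)
    d@S <- updateS(d, inst@M, cfg)
    d@Lambda <- updateDual(d, inst@M)
    expect_true(all(d@S[off] == 0))
    expect_true(all(d@Lambda[off] == 0))
  }
})

test_that("ADMM with lambda at the grid top reduces to the plain factorization", {
  toy <- makeToy(25, 20, 3, seed = 31)
  cfgA <- admmConfig(rank = 3, seed = 5, outerMaxIter = 200)
  cfgA@lambda <- max(lambdaGrid(toy@M, cfgA))
  dec <- robustNMF(toy@M, cfgA)
  expect_true(all(outlierMatrix(dec) == 0))

  cfgB <- solverConfig(rank = 3, seed = 5, outerMaxIter = 200, outerTol = 0)
  fit <- nmfBregman(maskedValues(toy@M), cfgB)
  relDiff <- norm(fittedMatrix(dec) - fittedMatrix(fit), "F") /
    norm(fittedMatrix(fit), "F")
  expect_lt(relDiff, 0.01)
})

test_that("low-rank completion recovers missing entries", {
  inst <- injectMissing(makeToy(40, 30, 3, seed = 51), 0.1, seed = 52)
  cfg <- admmConfig(rank = 3, seed = 6)
  cfg@lambda <- max(lambdaGrid(inst@M, cfg))
  dec <- robustNMF(inst@M, cfg)
  miss <- !observedMask(inst@M)
  rmse <- sqrt(mean((completedMatrix(dec)[miss] - inst@Mclean[miss])^2))
  rms <- sqrt(mean(inst@Mclean[!miss]^2))
  expect_lt(rmse, 0.1 * rms)
})

test_that("outlier mass is non-increasing along the lambda grid", {
  inst <- injectOutliers(makeToy(30, 20, 3, seed = 21), 0.05, seed = 22)
  cfg <- admmConfig(rank = 3, seed = 9, outerMaxIter = 400)
  grid <- lambdaGrid(inst@M, cfg, nPoints = 20)
  l1 <- vapply(grid[seq(2, 20, by = 4)], function(l) {
    cfg@lambda <- l
    sum(abs(outlierMatrix(suppressWarnings(robustNMF(inst@M, cfg)))))
  }, numeric(1))
  expect_true(all(diff(l1) <= 0.01 * utils::head(l1, -1)))
})

test_that("solver runs are reproducible from the seed", {
  inst <- injectOutliers(makeToy(15, 12, 2, seed = 71), 0.05, seed = 72)
  cfg <- admmConfig(rank = 2, lambda = 2, seed = 13, outerMaxIter = 50)
  a <- suppressWarnings(robustNMF(inst@M, cfg))
  b <- suppressWarnings(robustNMF(inst@M, cfg))
  expect_identical(a@Y, b@Y)
  expect_identical(a@S, b@S)
  expect_identical(factorU(a), factorU(b))
  expect_identical(dualMatrix(a), dualMatrix(b))
})
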