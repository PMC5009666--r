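test_that("entropic Bregman divergence matches its closed form and axioms", {
  X <- matrix(c(0.5, 1.2, 3, 0.07), 2, 2)
  expect_identical(bregmanDivergence(X, X), 0)

  # scalar case frozen from h(y) - h(x) - h'(x)(y - x) with h(x) = x ln x,
  # y = 1, x = e: value is e - 2
  expect_equal(bregmanDivergence(matrix(1), matrix(exp(1))),
               exp(1) - 2, tolerance = 1e-12)

  # non-negativity, and zero only at equality
  for (seed in 1:20) {
    set.seed(seed)
    Y <- matrix(runif(12, 0.05, 4), 3, 4)
    X <- matrix(runif(12, 0.05, 4), 3, 4)
    expect_gt(bregmanDivergence(Y, X), 0)
  }

  expect_error(bregmanDivergence(matrix(c(1, -1, 2, 3), 2), matrix(1, 2, 2)),
               "Y\\[2,1\\]")
  expect_error(bregmanDivergence(matrix(1, 2, 2), matrix(c(1, 1, 0, 1), 2)),
               "X\\[1,2\\]")
  expect_error(bregmanDivergence(matrix(1, 2, 2), matrix(1, 2, 3)),
               "dimensions")
})

test_that("fixed-point factor update honors its fixed point and stationarity", {
  set.seed(11)
  U0 <- matrix(runif(8, 0.2, 1), 4, 2)
  V0 <- matrix(runif(6, 0.2, 1), 3, 2)
  M <- U0 %*% t(V0)

  # exact factorization: U_prev is the fixed point, reached in one step
  up <- fixedPointUpdateU(M, U0, V0, rhoProx = 100)
  expect_equal(up$factor, U0, tolerance = 1e-12)
  expect_identical(up$iterations, 1L)
  expect_true(up$converged)

  # strict positivity and stationarity (M - UV^t)V = rho ln(U/U_prev)
  # at tolerance exit, on random instances
  for (seed in 1:5) {
    set.seed(seed)
    d <- sample(4:10, 1); n <- sample(4:8, 1); r <- sample(2:4, 1)
    M <- matrix(runif(d * n, 0, 3), d, n)
    Uprev <- matrix(runif(d * r, 0.1, 1), d, r)
    V <- matrix(runif(n * r, 0.1, 1), n, r)
    tol <- 1e-3; rho <- 100
    up <- fixedPointUpdateU(M, Uprev, V, rho, tol, 500L)
    expect_true(all(up$factor > 0))
    expect_true(up$converged)
    resid <- (M - up$factor %*% t(V)) %*% V - rho * log(up$factor / Uprev)
    expect_lt(max(abs(resid)), 10 * tol * rho)
  }
})

test_that("V update is the transposed U update", {
  set.seed(21)
  M <- matrix(runif(20, 0, 2), 5, 4)
  Vprev <- matrix(runif(12, 0.1, 1), 4, 3)
  U <- matrix(runif(15, 0.1, 1), 5, 3)
  a <- fixedPointUpdateV(M, Vprev, U, 50, 1e-4, 100L)
  b <- fixedPointUpdateU(t(M), Vprev, U, 50, 1e-4, 100L)
  expect_identical(a$factor, b$factor)
  expect_identical(a$iterations, b$iterations)
})

test_that("alternating scheme factorizes a rank-1 matrix to high accuracy", {
  set.seed(5)
  u <- runif(12, 0.2, 1); v <- runif(9, 0.2, 1)
  M <- u %*% t(v)
  fit <- nmfBregman(M, solverConfig(rank = 1, seed = 8,
                                    outerMaxIter = 2000, outerTol = 1e-12))
  rel <- errorTrace(fit)[fit@iterations] / norm(M, "F")
  expect_lt(rel, 1e-3)
  # independent cross-check: the classical multiplicative-update solver
  # reaches the same fit on this instance
  mu <- multiplicativeNMF(M, 1, iters = 500, seed = 8)
  expect_lt(norm(M - mu$U %*% t(mu$V), "F") / norm(M, "F"), 1e-3)
  expect_lt(norm(fittedMatrix(fit) - mu$U %*% t(mu$V), "F") / norm(M, "F"),
            2e-3)
})

test_that("alternating scheme decreases the error on a low-rank benchmark", {
  toy <- makeToy(25, 20, 4, seed = 31)
  cfg <- solverConfig(rank = 4, seed = 9, outerMaxIter = 60, outerTol = 0)
  fit <- nmfBregman(maskedValues(toy@M), cfg)
  e <- errorTrace(fit)
  expect_length(e, 60)
  expect_true(all(is.finite(e)) && all(e >= 0))
  expect_true(all(diff(e) <= 1e-8))       # monotone under the safeguard
  expect_lt(e[60], 0.5 * e[1])
  expect_true(all(factorU(fit) > 0) && all(factorV(fit) > 0))
})

test_that("plain NMF rejects invalid input and handles the zero matrix", {
  expect_error(nmfBregman(matrix(1, 3, 3), solverConfig(rank = 4)),
               "rank")
  expect_error(nmfBregman(matrix(c(1, -2, 3, 4), 2), solverConfig(rank = 1)),
               "non-negative")
  expect_warning(fit <- nmfBregman(matrix(0, 4, 3), solverConfig(rank = 2)),
                 "zero")
  expect_true(all(factorU(fit) > 0))
})
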