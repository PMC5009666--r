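# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: scalar subproblems are minimized numerically,
# and the classical multiplicative-update NMF serves as a cross-check for
# the Bregman solver on easy instances.

# golden-section minimizer of a scalar function on [lower, upper]
scalarMin <- function(f, lower, upper) {
  stats::optimize(f, c(lower, upper), tol = 1e-12)$minimum
}

# brute-force grid minimizer (coarse but derivative-free and assumption-free)
gridMin <- function(f, lower, upper, step = 1e-4) {
  xs <- seq(lower, upper, by = step)
  xs[which.min(vapply(xs, f, numeric(1)))]
}

# per-entry objective of the Y update (observed entry): quadratic coupling
# of the fit term, the multiplier term and the augmented penalty
yObjective <- function(a, lam, rho, m, s) {
  function(y) 0.5 * (y - a)^2 + lam * (m - y - s) + 0.5 * rho * (m - y - s)^2
}

# per-entry objective of the S update (observed entry)
sObjective <- function(lambda, lam, rho, m, y) {
  function(s) lambda * abs(s) + lam * (m - y - s) + 0.5 * rho * (m - y - s)^2
}

# classical multiplicative-update NMF (Frobenius loss), the field-standard
# baseline; independent of the entropic proximal path under test
multiplicativeNMF <- function(M, r, iters = 1000, seed = 1) {
  set.seed(seed)
  U <- matrix(stats::runif(nrow(M) * r, 0.1, 1), nrow(M), r)
  V <- matrix(stats::runif(ncol(M) * r, 0.1, 1), ncol(M), r)
  for (i in seq_len(iters)) {
    U <- U * (M %*% V) / (U %*% crossprod(V) + 1e-12)
    V <- V * (t(M) %*% U) / (V %*% crossprod(U) + 1e-12)
  }
  list(U = U, V = V)
}

supportScores <- function(Shat, Strue) {
  hat <- Shat != 0; true <- Strue != 0
  list(precision = sum(hat & true) / max(1L, sum(hat)),
       recall = sum(hat & true) / max(1L, sum(true)))
}

randomMasked <- function(d, n, seed, missFrac = 0) {
  set.seed(seed)
  vals <- matrix(stats::runif(d * n, 0.1, 5), d, n)
  observed <- matrix(TRUE, d, n)
  if (missFrac > 0)
    observed[sample(d * n, ceiling(missFrac * d * n))] <- FALSE
  MaskedMatrix(vals, observed)
}
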