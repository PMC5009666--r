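#' Entropic Bregman divergence between positive matrices
#'
#' Computes the divergence generated by the negative entropy
#' \eqn{h(x) = x \ln x}, summed over all entries:
#' \deqn{D_h(Y, X) = \sum_{ij} Y_{ij} \ln(Y_{ij}/X_{ij}) - Y_{ij} + X_{ij},}
#' the generalized Kullback-Leibler divergence.  It is non-negative, zero
#' exactly when \eqn{X = Y}, and finite only on the strictly positive
#' orthant — which is what makes it the natural proximal penalty for
#' non-negative factorization: iterates penalized by it can never leave
#' the feasible region.
#'
#' @param Y,X strictly positive numeric matrices of identical shape.
#' @return A single non-negative number.
#' @examples
#' bregmanDivergence(matrix(1), matrix(exp(1)))  # exp(1) - 2
#' @export
bregmanDivergence <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (!identical(dim(Y), dim(X)))
    stop("'Y' and 'X' must have identical dimensions")
  .checkPositive(Y, "Y")
  .checkPositive(X, "X")
  sum(Y * log(Y / X) - Y + X)
}

.checkPositive <- function(M, name) {
  bad <- which(!(is.finite(M) & M > 0))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(M))
    stop(sprintf("'%s' must be strictly positive and finite; %s[%d,%d] = %g",
                 name, name, ij[1], ij[2], M[bad[1]]))
  }
  invisible(TRUE)
}

# Exponent clamp for the multiplicative-exponential update: exp(50) ~ 5e21
# keeps iterates finite and strictly positive even when rhoProx is far too
# small for the data scale; the outer loop can then recover.
.EXP_CLAMP <- 50

#' Fixed-point solver for the entropic proximal factor update
#'
#' One outer step of the alternating scheme replaces U by the minimizer of
#' \eqn{\tfrac12 \|M - U V^t\|_F^2 + \rho D_h(U, U_{prev})} with the
#' entropic divergence [bregmanDivergence()].  The stationarity condition
#' \eqn{(M - U V^t) V = \rho \ln(U / U_{prev})} has no closed form, so it
#' is solved by the fixed-point iteration
#' \deqn{U^{(l+1)}_{ij} = \exp\!\big(\tfrac1\rho [(M - U^{(l)} V^t) V]_{ij}
#'   + \ln U_{prev,ij}\big),}
#' started at \eqn{U^{(0)} = U_{prev}} and stopped when the maximum
#' absolute entrywise change between successive iterates falls below
#' `innerTol`.  The exponential keeps every iterate strictly positive.
#'
#' The subproblem is convex but the fixed-point map is only locally
#' contractive, so the loop carries a monotonicity safeguard: the
#' subproblem objective is evaluated at every visited iterate and the best
#' one is returned.  When the iteration converges (the usual case) the
#' best iterate is the fixed point itself and the safeguard is inactive;
#' when the map oscillates or overflows, the safeguard returns the best
#' point seen — never worse than \eqn{U_{prev}} — so the outer scheme
#' cannot be destabilized by a wild inner iterate.
#'
#' @param M numeric d x n target matrix (any finite values).
#' @param Uprev strictly positive d x r matrix, the proximal center.
#' @param V strictly positive n x r matrix, held fixed.
#' @param rhoProx positive proximal weight.
#' @param innerTol stopping threshold on the max absolute change.
#' @param innerMaxIter iteration cap.
#' @param warnClamp emit a warning when the exponent clamp engages
#'   (default); the outer solvers aggregate these into one warning per run.
#' @return A list with components `factor` (the strictly positive update),
#'   `iterations` (inner iterations used), `converged` (whether the
#'   tolerance was met before the cap) and `clamped`.
#' @seealso [fixedPointUpdateV()] for the symmetric V update.
#' @export
fixedPointUpdateU <- function(M, Uprev, V, rhoProx = 100,
                              innerTol = 1e-3, innerMaxIter = 50L,
                              warnClamp = TRUE) {
  stopifnot(nrow(M) == nrow(Uprev), ncol(M) == nrow(V),
            ncol(Uprev) == ncol(V))
  .checkPositive(Uprev, "Uprev")
  .checkPositive(V, "V")
  lnUprev <- log(Uprev)
  U <- Uprev
  bestU <- Uprev
  bestObj <- Inf
  converged <- FALSE
  clamped <- FALSE
  l <- 0L
  repeat {
    R <- M - U %*% t(V)
    obj <- 0.5 * sum(R^2) +
      rhoProx * sum(U * (log(U) - lnUprev) - U + Uprev)
    if (obj < bestObj) { bestObj <- obj; bestU <- U }
    if (converged || l >= innerMaxIter) break
    l <- l + 1L
    expo <- R %*% V / rhoProx + lnUprev
    if (any(is.nan(expo)))
      stop(sprintf("NaN in fixed-point update at inner iteration %d", l))
    if (any(abs(expo) > .EXP_CLAMP)) {
      clamped <- TRUE
      expo <- pmin(pmax(expo, -.EXP_CLAMP), .EXP_CLAMP)
    }
    Unew <- exp(expo)
    converged <- max(abs(Unew - U)) < innerTol
    U <- Unew
  }
  if (clamped && warnClamp)
    warning("exponent clamped in fixed-point update; ",
            "consider a larger rhoProx for this data scale")
  list(factor = bestU, iterations = l, converged = converged,
       clamped = clamped)
}

#' @rdname fixedPointUpdateU
#' @param Vprev strictly positive n x r matrix, the proximal center of the
#'   V update.
#' @param U strictly positive d x r matrix, held fixed.
#' @details The V update is the same subproblem applied to \eqn{M^t} with
#'   the factor roles exchanged.
#' @export
fixedPointUpdateV <- function(M, Vprev, U, rhoProx = 100,
                              innerTol = 1e-3, innerMaxIter = 50L,
                              warnClamp = TRUE) {
  fixedPointUpdateU(t(M), Vprev, U, rhoProx = rhoProx,
                    innerTol = innerTol, innerMaxIter = innerMaxIter,
                    warnClamp = warnClamp)
}

#' Bregman-proximal alternating NMF
#'
#' Factorizes a fully observed non-negative matrix as \eqn{M \approx U V^t}
#' with strictly positive factors, by alternating the entropic proximal
#' updates of U and V ([fixedPointUpdateU()], [fixedPointUpdateV()]).  Each
#' outer iteration solves the two proximal subproblems to tolerance and
#' records the Frobenius error \eqn{\|M - U^{(k)} V^{(k)t}\|_F}; the loop
#' stops at `outerMaxIter` iterations or when the relative change of that
#' error falls below `outerTol`.
#'
#' @param M non-negative numeric matrix (or a fully observed
#'   [MaskedMatrix-class]).
#' @param config a [SolverConfig-class]; `rank`, `rhoProx`, the inner-loop
#'   controls, `outerTol`, `outerMaxIter` and `seed` are used.  Initial
#'   factors are drawn i.i.d. Uniform(positivityFloor, 1] from `seed`.
#' @return A [BregmanNMFFit-class] with the factors and the error trace.
#' @examples
#' toy <- makeToy(d = 20, n = 15, r = 3, seed = 7)
#' fit <- nmfBregman(maskedValues(toy@M), solverConfig(rank = 3, seed = 7))
#' fit
#' @export
nmfBregman <- function(M, config) {
  if (is(M, "MaskedMatrix")) {
    if (!all(M@observed))
      stop("nmfBregman requires a fully observed matrix; ",
           "use robustNMF for masked data")
    M <- M@values
  }
  M <- as.matrix(M)
  if (any(!is.finite(M))) stop("'M' must be finite and fully observed")
  if (any(M < 0)) {
    ij <- which(M < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("'M' must be non-negative; M[%d,%d] = %g",
                 ij[1], ij[2], M[ij[1], ij[2]]))
  }
  d <- nrow(M); n <- ncol(M); r <- config@rank
  if (r > min(d, n))
    stop(sprintf("rank %d exceeds min(dim(M)) = %d", r, min(d, n)))

  init <- .randomFactors(d, n, r, config)
  U <- init$U; V <- init$V
  if (all(M == 0)) {
    warning("'M' is identically zero; returning factors at the positivity floor")
    fl <- config@positivityFloor
    fp <- FactorPair(matrix(fl, d, r), matrix(fl, n, r))
    return(new("BregmanNMFFit", factors = fp,
               errTrace = norm(M - fittedMatrix(fp), "F"),
               converged = TRUE, iterations = 0L))
  }

  errTrace <- numeric(0)
  converged <- FALSE
  clamped <- FALSE
  k <- 0L
  while (k < config@outerMaxIter) {
    k <- k + 1L
    upU <- fixedPointUpdateU(M, U, V, config@rhoProx,
                             config@innerTol, config@innerMaxIter,
                             warnClamp = FALSE)
    U <- upU$factor
    upV <- fixedPointUpdateV(M, V, U, config@rhoProx,
                             config@innerTol, config@innerMaxIter,
                             warnClamp = FALSE)
    V <- upV$factor
    clamped <- clamped || upU$clamped || upV$clamped
    errTrace[k] <- norm(M - U %*% t(V), "F")
    if (k > 1L) {
      rel <- abs(errTrace[k] - errTrace[k - 1L]) /
        max(errTrace[k - 1L], .Machine$double.eps)
      if (rel < config@outerTol) { converged <- TRUE; break }
    }
  }
  if (clamped)
    warning("exponent clamp engaged during the run; ",
            "consider a larger rhoProx for this data scale")
  new("BregmanNMFFit", factors = FactorPair(U, V), errTrace = errTrace,
      converged = converged, iterations = k)
}

# Random strictly positive initial factors on (positivityFloor, 1],
# reproducible from config@seed.
.randomFactors <- function(d, n, r, config) {
  set.seed(config@seed)
  fl <- config@positivityFloor
  U <- matrix(stats::runif(d * r, min = fl, max = 1), d, r)
  V <- matrix(stats::runif(n * r, min = fl, max = 1), n, r)
  list(U = U, V = V)
}
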