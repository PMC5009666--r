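#' Initialize the robust decomposition
#'
#' Starting point of the ADMM: random strictly positive factors (seeded
#' from the config), zero outliers and multipliers, and Y set to the data
#' on the observed set with missing entries imputed by the mean of the
#' observed values of their row.  A row with no observed entry at all falls
#' back to the global mean of all observed entries (with a warning); this
#' case is degenerate but must not abort a run on sparsely observed data.
#'
#' @param M a [MaskedMatrix-class] with at least one observed entry.
#' @param config a [SolverConfig-class].
#' @return A [RobustDecomposition-class] at iteration zero (empty history).
#' @export
initializeDecomposition <- function(M, config) {
  obs <- M@observed
  if (!any(obs)) stop("'M' has no observed entries")
  d <- nrow(obs); n <- ncol(obs)
  init <- .randomFactors(d, n, config@rank, config)

  vals <- M@values
  globalMean <- mean(vals[obs])
  rowMeans <- vapply(seq_len(d), function(i) {
    oi <- obs[i, ]
    if (any(oi)) mean(vals[i, oi]) else NA_real_
  }, numeric(1))
  empty <- is.na(rowMeans)
  if (any(empty)) {
    warning(sprintf(
      "%d row(s) with no observed entries; imputing with the global mean",
      sum(empty)))
    rowMeans[empty] <- globalMean
  }
  Y <- matrix(rep(rowMeans, n), d, n)
  Y[obs] <- vals[obs]

  zero <- matrix(0, d, n)
  new("RobustDecomposition", Y = Y, S = zero,
      factors = FactorPair(init$U, init$V), Lambda = zero,
      observed = obs,
      history = data.frame(), converged = FALSE, iterations = 0L)
}

#' Closed-form Y update of the ADMM
#'
#' Minimizes the augmented Lagrangian in the denoised matrix Y with all
#' other variables fixed.  Off the observed set the data terms vanish and
#' the minimizer is the current low-rank fit; on the observed set the
#' quadratic coupling with the constraint M = Y + S pulls Y toward the
#' data:
#' \deqn{Y_{ij} = \frac{(UV^t)_{ij} + \Lambda_{ij} +
#'   \rho (M_{ij} - S_{ij})}{1 + \rho} \quad (i,j) \in \Omega,}
#' with \eqn{\rho} = `config@rhoAug`, and \eqn{Y_{ij} = (UV^t)_{ij}}
#' otherwise.
#'
#' @param decomp a [RobustDecomposition-class] (current U, V, S, Lambda).
#' @param M the [MaskedMatrix-class] being decomposed.
#' @param config a [SolverConfig-class] (`rhoAug` is used).
#' @return The updated numeric Y matrix.
#' @export
updateY <- function(decomp, M, config) {
  .updateY(fittedMatrix(decomp@factors), decomp@Lambda, decomp@S,
           M@values, M@observed, config@rhoAug)
}

.updateY <- function(UVt, Lam, S, vals, obs, rhoAug) {
  Y <- UVt
  Y[obs] <- (UVt[obs] + Lam[obs] + rhoAug * (vals[obs] - S[obs])) /
    (1 + rhoAug)
  Y
}

#' Soft-thresholding (proximal operator of the l1 norm)
#'
#' Returns the unique minimizer of \eqn{\tfrac12 (y - x)^2 + t |x|}:
#' `y - t` for `y > t`, `y + t` for `y < -t`, and 0 on the closed dead
#' zone \eqn{|y| \le t}.
#'
#' @param y numeric vector or matrix.
#' @param t non-negative threshold.
#' @return Object shaped like `y`.
#' @examples
#' softThreshold(c(-5, 0.5, 5), 2)  # -3, 0, 3
#' @export
softThreshold <- function(y, t) {
  if (length(t) != 1L || is.na(t) || t < 0)
    stop("'t' must be a single non-negative number")
  sign(y) * pmax(abs(y) - t, 0)
}

#' Closed-form S update of the ADMM
#'
#' Minimizes the augmented Lagrangian in the outlier matrix S: each entry
#' decouples, the minimizer off the observed set is 0, and on the observed
#' set it is the soft-thresholded scaled residual
#' \deqn{S_{ij} = \mathrm{soft}\big(M_{ij} - Y_{ij} + \Lambda_{ij}/\rho,\;
#'   \lambda/\rho\big),}
#' with \eqn{\rho} = `config@rhoAug` and \eqn{\lambda} = `config@lambda`.
#' Entries whose residual falls in the dead zone are declared outlier-free;
#' the l1 penalty thus performs the outlier detection.
#'
#' @inheritParams updateY
#' @return The updated numeric S matrix (zero off the observed set).
#' @export
updateS <- function(decomp, M, config) {
  if (config@lambda < 0) stop("'lambda' must be non-negative")
  .updateS(decomp@Y, decomp@Lambda, M@values, M@observed,
           config@rhoAug, config@lambda)
}

.updateS <- function(Y, Lam, vals, obs, rhoAug, lambda) {
  S <- matrix(0, nrow(Y), ncol(Y))
  resid <- vals[obs] - Y[obs] + Lam[obs] / rhoAug
  S[obs] <- softThreshold(resid, lambda / rhoAug)
  S
}

#' Dual ascent step of the ADMM
#'
#' Updates the multipliers of the constraint M = Y + S on the observed
#' set: \eqn{\Lambda_{ij} \leftarrow \Lambda_{ij} + \eta\,(M_{ij} - Y_{ij}
#' - S_{ij})} for observed (i,j) and 0 elsewhere (the constraint only
#' exists on the observed set).  The step `eta` defaults to 1, the plain
#' multiplier update; `config@dualStep` can scale it (e.g. to `rhoAug` for
#' the standard scaled ADMM step).
#'
#' @param decomp a [RobustDecomposition-class] (current Y, S, Lambda).
#' @param M the [MaskedMatrix-class] being decomposed.
#' @param eta positive dual step length.
#' @return The updated numeric Lambda matrix.
#' @export
updateDual <- function(decomp, M, eta = 1) {
  obs <- M@observed
  Lam <- decomp@Lambda
  Lam[obs] <- Lam[obs] + eta * (M@values[obs] - decomp@Y[obs] - decomp@S[obs])
  Lam
}

#' Robust NMF by Bregman-proximal ADMM
#'
#' Solves the masked, outlier-robust factorization problem
#' \deqn{\min_{Y, S, U, V} \tfrac12 \sum_{(i,j)\in\Omega}
#'   (Y_{ij} - (UV^t)_{ij})^2 + \lambda \|S\|_1
#'   \quad \text{s.t. } M = Y + S \text{ on } \Omega,}
#' by an augmented-Lagrangian ADMM.  Each outer iteration performs, in
#' order: the closed-form [updateY()], the soft-threshold [updateS()], the
#' entropic proximal factor updates ([fixedPointUpdateU()] then
#' [fixedPointUpdateV()]) fitted to the current Y (the denoised, fully
#' defined matrix — the data matrix itself has holes and outliers), and
#' the dual ascent [updateDual()].  The run stops at `outerMaxIter`
#' iterations or when both the primal residual \eqn{\max_\Omega |M - Y -
#' S|} and the Frobenius distance between successive multipliers fall
#' below `outerTol`.
#'
#' The completed matrix exposed to users is Y; on unobserved entries it
#' coincides with the low-rank fit \eqn{UV^t}.
#'
#' @param M a [MaskedMatrix-class] (or plain matrix, taken fully observed
#'   with `NA` entries treated as missing).
#' @param config a [SolverConfig-class]; see [admmConfig()] for defaults
#'   suited to this solver.
#' @return A [RobustDecomposition-class].
#' @examples
#' inst <- injectOutliers(makeToy(d = 20, n = 15, r = 3, seed = 3),
#'                        fraction = 0.05, seed = 4)
#' dec <- robustNMF(inst@M, admmConfig(rank = 3, lambda = 5, seed = 3,
#'                                     outerMaxIter = 50))
#' dec
#' @export
robustNMF <- function(M, config) {
  if (!is(M, "MaskedMatrix")) M <- MaskedMatrix(M)
  validObject(config)
  decomp <- initializeDecomposition(M, config)
  obs <- M@observed
  vals <- M@values
  obsNorm <- sqrt(sum(vals[obs]^2))

  U <- decomp@factors@U
  V <- decomp@factors@V
  Y <- decomp@Y
  S <- decomp@S
  Lam <- decomp@Lambda

  hist <- vector("list", config@outerMaxIter)
  converged <- FALSE
  clamped <- FALSE
  k <- 0L
  while (k < config@outerMaxIter) {
    k <- k + 1L
    UVt <- U %*% t(V)
    Y <- .updateY(UVt, Lam, S, vals, obs, config@rhoAug)
    .checkFinite(Y, "Y", k)
    S <- .updateS(Y, Lam, vals, obs, config@rhoAug, config@lambda)
    .checkFinite(S, "S", k)
    upU <- fixedPointUpdateU(Y, U, V, config@rhoProx,
                             config@innerTol, config@innerMaxIter,
                             warnClamp = FALSE)
    U <- upU$factor
    .checkFinite(U, "U", k)
    upV <- fixedPointUpdateV(Y, V, U, config@rhoProx,
                             config@innerTol, config@innerMaxIter,
                             warnClamp = FALSE)
    V <- upV$factor
    .checkFinite(V, "V", k)
    clamped <- clamped || upU$clamped || upV$clamped
    resid <- vals[obs] - Y[obs] - S[obs]
    LamNew <- Lam
    LamNew[obs] <- Lam[obs] + config@dualStep * resid
    .checkFinite(LamNew, "Lambda", k)
    dualDelta <- sqrt(sum((LamNew - Lam)^2))
    Lam <- LamNew

    UVt <- U %*% t(V)
    hist[[k]] <- data.frame(
      iteration = k,
      primal = max(abs(resid)),
      dualDelta = dualDelta,
      relErr = sqrt(sum((vals[obs] - UVt[obs])^2)) /
        max(obsNorm, .Machine$double.eps),
      minU = min(U), minV = min(V),
      innerU = upU$iterations, innerV = upV$iterations)

    if (hist[[k]]$primal < config@outerTol &&
        dualDelta < config@outerTol) { converged <- TRUE; break }
  }

  if (clamped)
    warning("exponent clamp engaged during the run; ",
            "consider a larger rhoProx for this data scale")
  new("RobustDecomposition", Y = Y, S = S, factors = FactorPair(U, V),
      Lambda = Lam, observed = obs,
      history = do.call(rbind, hist[seq_len(k)]),
      converged = converged, iterations = k)
}

.checkFinite <- function(X, name, iter) {
  if (any(!is.finite(X)))
    stop(sprintf("non-finite value in %s at outer iteration %d",
                 name, iter))
  invisible(TRUE)
}
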