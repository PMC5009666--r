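#' Candidate grid for the outlier penalty
#'
#' Builds a log-spaced grid of candidate values for the l1 weight lambda.
#' The top of the grid is the smallest value for which the very first
#' S update of the ADMM thresholds every observed residual to zero: by the
#' dead zone of [updateS()] this is
#' \eqn{\lambda_{max} = \rho_{aug} \max_{(i,j)\in\Omega} |M_{ij} -
#' Y^{(1)}_{ij}|}, where \eqn{Y^{(1)}} is the first Y update from the
#' seeded initialization (the multipliers are still zero there).  Running
#' the solver at \eqn{\lambda_{max}} therefore starts — and in practice
#' stays — at S = 0, the pure completion fit; the grid spans three decades
#' below it.
#'
#' @param M a [MaskedMatrix-class].
#' @param config a [SolverConfig-class] (rank, rhoAug and seed matter).
#' @param nPoints number of grid points (>= 2; default 20).
#' @return Strictly increasing numeric vector of length `nPoints` from
#'   \eqn{\lambda_{max}/1000} to \eqn{\lambda_{max}}.  If the initial
#'   residual is identically zero the grid degenerates to `1` with a
#'   warning.
#' @export
lambdaGrid <- function(M, config, nPoints = 20L) {
  if (nPoints < 2L) stop("'nPoints' must be at least 2")
  decomp <- initializeDecomposition(M, config)
  Y1 <- updateY(decomp, M, config)
  obs <- M@observed
  resid <- max(abs(M@values[obs] - Y1[obs]))
  lamMax <- config@rhoAug * resid
  if (lamMax <= .Machine$double.eps) {
    warning("all initial residuals are zero; returning the degenerate grid {1}")
    return(1)
  }
  grid <- exp(seq(log(lamMax / 1000), log(lamMax), length.out = nPoints))
  grid[1] <- lamMax / 1000
  grid[nPoints] <- lamMax
  grid
}

#' Artificially mask observed entries for cross-validation
#'
#' Samples `s` observed entries uniformly at random without replacement
#' and declares them missing in the returned mask; their positions and
#' true values are retained for scoring.
#'
#' @param M a [MaskedMatrix-class].
#' @param s number of entries to hold out (1 <= s < number observed).
#' @param seed integer seed; the split is reproducible from it.
#' @return A list with `reduced` (the [MaskedMatrix-class] with the
#'   holdout masked) and `holdout` (data.frame with columns `row`, `col`,
#'   `value`).
#' @export
holdoutSplit <- function(M, s, seed) {
  obsIdx <- which(M@observed)
  if (s < 1L || s >= length(obsIdx))
    stop(sprintf("'s' must lie in [1, %d)", length(obsIdx)))
  set.seed(seed)
  pick <- sample(obsIdx, s)
  ij <- arrayInd(pick, dim(M@observed))
  holdout <- data.frame(row = ij[, 1], col = ij[, 2],
                        value = M@values[pick])
  observed <- M@observed
  observed[pick] <- FALSE
  list(reduced = MaskedMatrix(M@values, observed, M@labels),
       holdout = holdout)
}

#' Holdout error of the robust solver at one lambda
#'
#' Runs [robustNMF()] on the reduced mask (the original mask minus the
#' holdout entries) with the given lambda and returns the mean squared
#' error between the held-out true values and the completed matrix Y at
#' those positions.
#'
#' @param M the original [MaskedMatrix-class].
#' @param holdout data.frame (`row`, `col`, `value`) as produced by
#'   [holdoutSplit()].
#' @param lam the candidate lambda.
#' @param config a [SolverConfig-class] (its `lambda` is overridden).
#' @return Mean squared holdout error (non-negative scalar).
#' @export
scoreLambda <- function(M, holdout, lam, config) {
  if (!nrow(holdout)) stop("'holdout' must be non-empty")
  observed <- M@observed
  pos <- cbind(holdout$row, holdout$col)
  observed[pos] <- FALSE
  reduced <- MaskedMatrix(M@values, observed, M@labels)
  cfg <- config
  cfg@lambda <- lam
  dec <- tryCatch(robustNMF(reduced, cfg), error = function(e)
    stop(sprintf("solver failed at lambda = %g: %s", lam,
                 conditionMessage(e)), call. = FALSE))
  mean((holdout$value - dec@Y[pos])^2)
}

#' Select the outlier penalty by holdout cross-validation
#'
#' Builds the lambda grid ([lambdaGrid()]), draws one holdout split shared
#' across all grid points (so the per-lambda errors are directly
#' comparable), scores every candidate with [scoreLambda()], and selects
#' the grid point with the smallest mean squared holdout error, breaking
#' ties toward the smallest lambda.  Setting `repeats > 1` averages the
#' error curve over independent splits.
#'
#' @param M a [MaskedMatrix-class].
#' @param config a [SolverConfig-class].
#' @param nPoints grid size (default 20).
#' @param s holdout size; defaults to 5 percent of the observed entries.
#' @param seed integer seed for the split(s); defaults to `config@seed`.
#' @param repeats number of independent splits to average over (default 1).
#' @return A [CVReport-class].
#' @examples
#' inst <- injectOutliers(makeToy(20, 15, 2, seed = 11), 0.05, seed = 12)
#' rep <- selectLambda(inst@M, admmConfig(rank = 2, seed = 11,
#'                                        outerMaxIter = 40), nPoints = 4)
#' rep
#' @export
selectLambda <- function(M, config, nPoints = 20L, s = NULL,
                         seed = config@seed, repeats = 1L) {
  if (is.null(s)) s <- max(1L, ceiling(0.05 * nObserved(M)))
  grid <- lambdaGrid(M, config, nPoints)
  holdouts <- lapply(seq_len(repeats), function(r)
    holdoutSplit(M, s, seed = seed + r - 1L)$holdout)
  errs <- rowMeans(vapply(holdouts, function(h)
    vapply(grid, function(lam) scoreLambda(M, h, lam, config),
           numeric(1)),
    numeric(length(grid))))
  sel <- grid[which.min(errs)]  # which.min takes the first, i.e. smallest
  new("CVReport", grid = grid, holdouts = holdouts, errs = errs,
      selected = sel, seed = as.integer(seed))
}
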