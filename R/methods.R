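#' @rdname accessors
setMethod("maskedValues", "MaskedMatrix", function(object) object@values)
#' @rdname accessors
setMethod("observedMask", "MaskedMatrix", function(object) object@observed)
#' @rdname accessors
setMethod("sampleLabels", "MaskedMatrix", function(object) object@labels)

#' @describeIn MaskedMatrix-class dimensions of the data matrix.
#' @param x a `MaskedMatrix`.
#' @export
setMethod("dim", "MaskedMatrix", function(x) dim(x@values))

#' Number of observed entries
#' @param object a [MaskedMatrix-class].
#' @return integer count of observed entries.
#' @export
nObserved <- function(object) sum(object@observed)

setMethod("show", "MaskedMatrix", function(object) {
  d <- dim(object@values)
  cat(sprintf("MaskedMatrix: %d x %d, %d/%d entries observed (%.1f%%)\n",
              d[1], d[2], nObserved(object), prod(d),
              100 * nObserved(object) / prod(d)))
  if (length(object@labels))
    cat(sprintf("  row labels: %s\n",
                paste(utils::head(unique(object@labels), 5),
                      collapse = ", ")))
})

#' @rdname accessors
setMethod("factorU", "FactorPair", function(object) object@U)
#' @rdname accessors
setMethod("factorV", "FactorPair", function(object) object@V)
#' @rdname accessors
setMethod("factorRank", "FactorPair", function(object) object@rank)
#' @rdname accessors
setMethod("fittedMatrix", "FactorPair",
          function(object) object@U %*% t(object@V))

setMethod("show", "FactorPair", function(object) {
  cat(sprintf("FactorPair: U %d x %d, V %d x %d (rank %d)\n",
              nrow(object@U), ncol(object@U), nrow(object@V),
              ncol(object@V), object@rank))
})

setMethod("show", "SolverConfig", function(object) {
  cat(sprintf(paste0(
    "SolverConfig: rank=%d rhoProx=%g rhoAug=%g lambda=%g\n",
    "  inner: tol=%g maxIter=%d   outer: tol=%g maxIter=%d\n",
    "  positivityFloor=%g dualStep=%g seed=%d\n"),
    object@rank, object@rhoProx, object@rhoAug, object@lambda,
    object@innerTol, object@innerMaxIter, object@outerTol,
    object@outerMaxIter, object@positivityFloor, object@dualStep,
    object@seed))
})

#' @rdname accessors
setMethod("factorU", "BregmanNMFFit", function(object) object@factors@U)
#' @rdname accessors
setMethod("factorV", "BregmanNMFFit", function(object) object@factors@V)
#' @rdname accessors
setMethod("factorRank", "BregmanNMFFit", function(object) object@factors@rank)
#' @rdname accessors
setMethod("fittedMatrix", "BregmanNMFFit",
          function(object) fittedMatrix(object@factors))
#' @rdname accessors
setMethod("errorTrace", "BregmanNMFFit", function(object) object@errTrace)

setMethod("show", "BregmanNMFFit", function(object) {
  e <- object@errTrace
  cat(sprintf(paste0(
    "BregmanNMFFit: rank %d, %d outer iterations (%s)\n",
    "  Frobenius error: %.4g -> %.4g\n"),
    object@factors@rank, object@iterations,
    if (object@converged) "converged" else "iteration cap reached",
    e[1], e[length(e)]))
})

#' @rdname accessors
setMethod("completedMatrix", "RobustDecomposition", function(object) object@Y)
#' @rdname accessors
setMethod("outlierMatrix", "RobustDecomposition", function(object) object@S)
#' @rdname accessors
setMethod("dualMatrix", "RobustDecomposition", function(object) object@Lambda)
#' @rdname accessors
setMethod("factorU", "RobustDecomposition", function(object) object@factors@U)
#' @rdname accessors
setMethod("factorV", "RobustDecomposition", function(object) object@factors@V)
#' @rdname accessors
setMethod("fittedMatrix", "RobustDecomposition",
          function(object) fittedMatrix(object@factors))
#' @rdname accessors
setMethod("solverHistory", "RobustDecomposition",
          function(object) object@history)

setMethod("show", "RobustDecomposition", function(object) {
  h <- object@history
  cat(sprintf(paste0(
    "RobustDecomposition: %d x %d, rank %d, %d iterations (%s)\n",
    "  outliers detected: %d nonzero entries of S\n",
    "  final primal residual %.3g, dual distance %.3g, rel. error %.3g\n"),
    nrow(object@Y), ncol(object@Y), object@factors@rank,
    object@iterations,
    if (object@converged) "converged" else "iteration cap reached",
    sum(object@S != 0),
    h$primal[nrow(h)], h$dualDelta[nrow(h)], h$relErr[nrow(h)]))
})

setMethod("show", "CVReport", function(object) {
  cat(sprintf(paste0(
    "CVReport: %d-point lambda grid [%.4g, %.4g], %d held-out entries\n",
    "  selected lambda = %.6g (holdout MSE %.4g)\n"),
    length(object@grid), min(object@grid), max(object@grid),
    nrow(object@holdouts[[1]]), object@selected,
    min(object@errs)))
})

setMethod("show", "SyntheticInstance", function(object) {
  d <- dim(object@Mclean)
  cat(sprintf(paste0(
    "SyntheticInstance: %d x %d, rank %d ground truth\n",
    "  outliers: %d, missing: %d, noise sigma: %g, seed: %d\n"),
    d[1], d[2], ncol(object@U0), sum(object@Strue != 0),
    prod(d) - nObserved(object@M), object@noiseSigma, object@seed))
})
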