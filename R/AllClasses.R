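#' @import methods
NULL

#' Masked non-negative data matrix
#'
#' Container for a numeric data matrix together with its observation set
#' \eqn{\Omega}: the boolean mask flagging which entries were actually
#' measured.  Unobserved entries may hold any placeholder (conventionally
#' `NA`) and are never read by the solvers.  Observed entries must be finite;
#' gene-expression data are non-negative, but entries corrupted by gross
#' outliers may fall outside the physical range, so non-negativity is
#' enforced by the entry points that require it ([nmfBregman()], the file
#' reader) rather than by the container.
#'
#' @slot values numeric matrix (d x n).
#' @slot observed logical matrix of the same shape; `TRUE` marks a measured
#'   entry.
#' @slot labels optional character vector of per-row labels (e.g. tumor
#'   state), length 0 or d.
#'
#' @seealso [MaskedMatrix()] for the user constructor.
#' @export
setClass("MaskedMatrix",
  slots = c(values = "matrix", observed = "matrix", labels = "character"))

setValidity("MaskedMatrix", function(object) {
  v <- object@values; o <- object@observed
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  if (!is.logical(o)) return("'observed' must be a logical matrix")
  if (!identical(dim(v), dim(o)))
    return("'values' and 'observed' must have identical dimensions")
  if (anyNA(o)) return("'observed' may not contain NA")
  ov <- v[o]
  if (length(ov) && any(!is.finite(ov)))
    return("observed entries must be finite")
  if (length(object@labels) && length(object@labels) != nrow(v))
    return("'labels' must be empty or have one entry per row")
  TRUE
})

#' Construct a MaskedMatrix
#'
#' @param values numeric matrix; `NA`/`NaN` entries are treated as
#'   unobserved when `observed` is not given.
#' @param observed logical matrix marking measured entries; defaults to
#'   `!is.na(values)`.
#' @param labels optional character vector of row labels.
#' @return A [MaskedMatrix-class] object.
#' @examples
#' m <- matrix(c(1, 2, NA, 4), 2, 2)
#' MaskedMatrix(m)
#' @export
MaskedMatrix <- function(values, observed = !is.na(values),
                         labels = character()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  observed <- as.matrix(observed)
  storage.mode(observed) <- "logical"
  new("MaskedMatrix", values = values, observed = observed,
      labels = as.character(labels))
}

#' Pair of strictly positive factors
#'
#' Holds the factors of the approximation \eqn{M \approx U V^t}: `U` is
#' d x r (sample loadings), `V` is n x r (feature loadings).  The entropic
#' update works on logarithms of the factors, so all entries must be
#' strictly positive.
#'
#' @slot U numeric matrix, d x r, strictly positive.
#' @slot V numeric matrix, n x r, strictly positive.
#' @slot rank integer, the common column count r.
#' @export
setClass("FactorPair",
  slots = c(U = "matrix", V = "matrix", rank = "integer"))

setValidity("FactorPair", function(object) {
  if (ncol(object@U) != object@rank || ncol(object@V) != object@rank)
    return("column counts of U and V must both equal 'rank'")
  if (object@rank < 1L) return("'rank' must be a positive integer")
  if (any(!is.finite(object@U)) || any(!is.finite(object@V)))
    return("factors must be finite")
  if (any(object@U <= 0) || any(object@V <= 0))
    return("all factor entries must be strictly positive")
  TRUE
})

#' @rdname FactorPair-class
#' @param U,V strictly positive numeric matrices with equal column counts.
#' @return A [FactorPair-class] object.
#' @export
FactorPair <- function(U, V) {
  new("FactorPair", U = as.matrix(U), V = as.matrix(V),
      rank = as.integer(ncol(U)))
}

#' Solver configuration
#'
#' Bundles every tunable of the Bregman-proximal NMF and of the robust
#' ADMM.  The Bregman proximal weight and the augmented-Lagrangian penalty
#' are distinct parameters even though both act as a "rho": the former
#' damps the factor updates, the latter enforces the splitting constraint
#' M = Y + S on the observed entries.
#'
#' @slot rhoProx positive real, Bregman proximal weight for the U/V updates.
#' @slot rhoAug positive real, augmented-Lagrangian penalty.
#' @slot lambda non-negative real, l1 weight on the outlier matrix S.
#' @slot rank positive integer, target factorization rank r.
#' @slot innerTol positive real, stop threshold (max absolute entrywise
#'   change) for the fixed-point inner loop.
#' @slot innerMaxIter positive integer, inner iteration cap.
#' @slot outerTol positive real, outer stopping tolerance.
#' @slot outerMaxIter positive integer, outer iteration cap.
#' @slot positivityFloor small positive real, lower bound used when drawing
#'   random initial factors.
#' @slot dualStep positive real multiplying the dual ascent step (1 follows
#'   the plain multiplier update; set to `rhoAug` for the standard scaled
#'   ADMM step).
#' @slot seed integer seed for the random factor initialization.
#' @export
setClass("SolverConfig",
  slots = c(rhoProx = "numeric", rhoAug = "numeric", lambda = "numeric",
            rank = "integer", innerTol = "numeric", innerMaxIter = "integer",
            outerTol = "numeric", outerMaxIter = "integer",
            positivityFloor = "numeric", dualStep = "numeric",
            seed = "integer"))

setValidity("SolverConfig", function(object) {
  if (object@rhoProx <= 0) return("'rhoProx' must be positive")
  if (object@rhoAug <= 0) return("'rhoAug' must be positive")
  if (object@lambda < 0) return("'lambda' must be non-negative")
  if (object@rank < 1L) return("'rank' must be a positive integer")
  if (object@innerTol <= 0) return("'innerTol' must be positive")
  if (object@positivityFloor <= 0 || object@positivityFloor >= 1)
    return("'positivityFloor' must lie strictly between 0 and 1")
  if (object@innerMaxIter < 1L || object@outerMaxIter < 1L)
    return("iteration caps must be positive")
  if (object@dualStep <= 0) return("'dualStep' must be positive")
  TRUE
})

#' @rdname SolverConfig-class
#'
#' @param rank target factorization rank r.
#' @param rhoProx Bregman proximal weight (default 100, the toy-experiment
#'   value).
#' @param rhoAug augmented-Lagrangian penalty (default 100).
#' @param lambda outlier-sparsity weight (default 1; in practice chosen by
#'   [selectLambda()]).
#' @param innerTol fixed-point stopping threshold (default 1e-3).
#' @param innerMaxIter inner iteration cap (default 50).
#' @param outerTol outer stopping tolerance (default 1e-6 on the relative
#'   error change of the alternating scheme).
#' @param outerMaxIter outer iteration cap (default 100).
#' @param positivityFloor lower bound for random factor draws (default 1e-8).
#' @param dualStep dual ascent step multiplier (default 1).
#' @param seed integer RNG seed (default 1).
#' @return A validated [SolverConfig-class] object.
#' @examples
#' solverConfig(rank = 4)
#' admmConfig(rank = 4, lambda = 2)
#' @export
solverConfig <- function(rank, rhoProx = 100, rhoAug = 100, lambda = 1,
                         innerTol = 1e-3, innerMaxIter = 50L,
                         outerTol = 1e-6, outerMaxIter = 100L,
                         positivityFloor = 1e-8, dualStep = 1,
                         seed = 1L) {
  new("SolverConfig", rhoProx = rhoProx, rhoAug = rhoAug, lambda = lambda,
      rank = as.integer(rank), innerTol = innerTol,
      innerMaxIter = as.integer(innerMaxIter), outerTol = outerTol,
      outerMaxIter = as.integer(outerMaxIter),
      positivityFloor = positivityFloor, dualStep = dualStep,
      seed = as.integer(seed))
}

#' @rdname SolverConfig-class
#'
#' @details `admmConfig()` is `solverConfig()` with defaults suited to the
#'   robust ADMM: `outerTol = 1e-5` (applied to both the primal residual on
#'   the observed set and the Frobenius distance of successive multipliers)
#'   and `outerMaxIter = 1000`.  The cap follows the solver's dynamics:
#'   with the unit dual step the constraint residual contracts by
#'   `rhoAug / (1 + rhoAug)` per iteration, a time constant of about
#'   `rhoAug` iterations, so several hundred iterations are needed at the
#'   default `rhoAug = 100` before the outlier support is resolved.
#' @param ... passed on to `solverConfig()`.
#' @export
admmConfig <- function(rank, ..., outerTol = 1e-5, outerMaxIter = 1000L) {
  solverConfig(rank = rank, ..., outerTol = outerTol,
               outerMaxIter = outerMaxIter)
}

#' Plain Bregman-proximal NMF fit
#'
#' Result of [nmfBregman()]: the factor pair together with the Frobenius
#' error trace of the alternating scheme.
#'
#' @slot factors a [FactorPair-class].
#' @slot errTrace numeric vector, \eqn{\|M - U^{(k)}V^{(k)t}\|_F} per outer
#'   iteration.
#' @slot converged logical, whether the relative-change criterion fired
#'   before the iteration cap.
#' @slot iterations integer, outer iterations performed.
#' @export
setClass("BregmanNMFFit",
  slots = c(factors = "FactorPair", errTrace = "numeric",
            converged = "logical", iterations = "integer"))

#' Robust decomposition state
#'
#' Full state of the augmented-Lagrangian ADMM: the denoised/completed
#' matrix Y, the sparse outlier matrix S (supported on the observed set),
#' the positive factors, the dual multipliers, and per-iteration
#' diagnostics.
#'
#' @slot Y numeric d x n matrix, denoised and completed data.
#' @slot S numeric d x n matrix of outliers, zero off the observed set.
#' @slot factors a [FactorPair-class].
#' @slot Lambda numeric d x n dual matrix, zero off the observed set.
#' @slot observed logical mask the decomposition was fitted under.
#' @slot history data.frame of per-iteration diagnostics: `primal` (max
#'   constraint residual on the observed set), `dualDelta` (Frobenius
#'   distance of successive multipliers), `relErr` (relative factorization
#'   error on the observed set), `minU`/`minV` (smallest factor entries),
#'   `innerU`/`innerV` (inner iterations used).
#' @slot converged logical.
#' @slot iterations integer.
#' @export
setClass("RobustDecomposition",
  slots = c(Y = "matrix", S = "matrix", factors = "FactorPair",
            Lambda = "matrix", observed = "matrix",
            history = "data.frame", converged = "logical",
            iterations = "integer"))

setValidity("RobustDecomposition", function(object) {
  off <- !object@observed
  if (any(object@S[off] != 0)) return("S must vanish off the observed set")
  if (any(object@Lambda[off] != 0))
    return("Lambda must vanish off the observed set")
  if (!identical(dim(object@Y), dim(object@S)) ||
      !identical(dim(object@Y), dim(object@Lambda)))
    return("Y, S and Lambda must share dimensions")
  TRUE
})

#' Cross-validation report for the outlier penalty
#'
#' Result of [selectLambda()]: the lambda grid, the held-out entries, the
#' mean squared holdout error per grid point, and the selected value.
#'
#' @slot grid increasing numeric vector of candidate lambda values.
#' @slot holdouts list of data.frames (`row`, `col`, `value`), one per
#'   repeat, of entries artificially declared missing.
#' @slot errs numeric vector, mean squared holdout error per grid point
#'   (averaged over repeats).
#' @slot selected numeric, the grid point minimizing the error (ties break
#'   to the smallest lambda).
#' @slot seed integer seed the splits were drawn from.
#' @export
setClass("CVReport",
  slots = c(grid = "numeric", holdouts = "list", errs = "numeric",
            selected = "numeric", seed = "integer"))

setValidity("CVReport", function(object) {
  if (length(object@errs) != length(object@grid))
    return("one error value per grid point required")
  if (length(object@grid) > 1 && any(diff(object@grid) <= 0))
    return("'grid' must be strictly increasing")
  if (any(!is.finite(object@errs)) || any(object@errs < 0))
    return("errors must be finite and non-negative")
  TRUE
})

#' Synthetic benchmark instance
#'
#' Ground truth and corrupted observation of a low-rank non-negative
#' matrix: `Mclean = U0 V0^t` exactly, plus (optionally) sparse outliers,
#' missing entries and dense noise applied in the canonical order
#' outliers -> missingness -> noise.  Every instance is regenerable
#' bit-exactly from the parameters stored in `metadata`.
#'
#' @slot Mclean numeric d x n matrix, the uncorrupted low-rank product.
#' @slot U0,V0 ground-truth factors.
#' @slot M a [MaskedMatrix-class], the corrupted observation.
#' @slot Strue numeric d x n matrix of injected outliers (zero elsewhere).
#' @slot noiseSigma non-negative real, relative noise level applied.
#' @slot seed integer, seed of the base instance.
#' @slot metadata named list recording the full generation provenance.
#' @export
setClass("SyntheticInstance",
  slots = c(Mclean = "matrix", U0 = "matrix", V0 = "matrix",
            M = "MaskedMatrix", Strue = "matrix", noiseSigma = "numeric",
            seed = "integer", metadata = "list"))

setValidity("SyntheticInstance", function(object) {
  if (max(abs(object@Mclean - object@U0 %*% t(object@V0))) > 1e-10)
    return("'Mclean' must equal U0 V0^t exactly")
  if (!identical(dim(object@Strue), dim(object@Mclean)))
    return("'Strue' must have the data dimensions")
  inj <- which(object@Strue != 0, arr.ind = TRUE)
  if (nrow(inj) && !all(object@M@observed[inj]))
    return("injected outlier positions must be observed")
  TRUE
})
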