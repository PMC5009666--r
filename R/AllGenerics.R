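#' @name accessors
#' @title Accessors for BregmanNMF objects
#'
#' @description Slot access for the package's S4 classes.  `maskedValues()`
#' and `observedMask()` return the data and the observation mask;
#' `sampleLabels()` the optional per-sample labels; `factorU()`, `factorV()`
#' and `factorRank()` the factors; `fittedMatrix()` the low-rank product
#' \eqn{U V^t}; `completedMatrix()` the denoised/completed matrix Y;
#' `outlierMatrix()` the sparse outlier matrix S; `dualMatrix()` the
#' multipliers; `errorTrace()` the per-iteration Frobenius error of the
#' alternating scheme; `solverHistory()` the ADMM diagnostics.
#'
#' @param object an object of the appropriate class.
#' @return The slot value (a matrix, vector or data.frame as documented).
NULL

#' @rdname accessors
#' @export
setGeneric("maskedValues", function(object) standardGeneric("maskedValues"))
#' @rdname accessors
#' @export
setGeneric("observedMask", function(object) standardGeneric("observedMask"))
#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(object) standardGeneric("sampleLabels"))
#' @rdname accessors
#' @export
setGeneric("factorU", function(object) standardGeneric("factorU"))
#' @rdname accessors
#' @export
setGeneric("factorV", function(object) standardGeneric("factorV"))
#' @rdname accessors
#' @export
setGeneric("factorRank", function(object) standardGeneric("factorRank"))
#' @rdname accessors
#' @export
setGeneric("fittedMatrix", function(object) standardGeneric("fittedMatrix"))
#' @rdname accessors
#' @export
setGeneric("completedMatrix",
           function(object) standardGeneric("completedMatrix"))
#' @rdname accessors
#' @export
setGeneric("outlierMatrix", function(object) standardGeneric("outlierMatrix"))
#' @rdname accessors
#' @export
setGeneric("dualMatrix", function(object) standardGeneric("dualMatrix"))
#' @rdname accessors
#' @export
setGeneric("errorTrace", function(object) standardGeneric("errorTrace"))
#' @rdname accessors
#' @export
setGeneric("solverHistory", function(object) standardGeneric("solverHistory"))
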