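#' Read a data matrix with missing entries
#'
#' Reads CSV/TSV (dense; empty cells, `NA` and `NaN` are missing) or
#' MatrixMarket files into a [MaskedMatrix-class].  The orientation must
#' be stated explicitly — NMF conventions differ between fields, and a
#' silently guessed orientation swaps the meaning of the two factors.
#' Internally the package standardizes to rows = samples, so `factorU()`
#' holds sample loadings and `factorV()` feature loadings.
#'
#' For MatrixMarket input the file is taken at face value as a dense
#' object in sparse storage: entries absent from the coordinate list are
#' observed zeros, and stored `NaN` entries are missing.
#'
#' @param path file to read.
#' @param format `"csv"`, `"tsv"`, `"mtx"`, or `"auto"` (from the
#'   extension).
#' @param orientation `"samples-rows"` or `"samples-cols"` (required).
#' @param labelColumn if `TRUE` the first column (samples-rows CSV/TSV
#'   only) is a non-numeric sample label (e.g. tumor state) and is split
#'   off into `sampleLabels()`.
#' @param allowNegative observed negative values are a domain error for
#'   non-negative data (default); set `TRUE` when reading data whose gross
#'   corruptions may leave the physical range.
#' @return A [MaskedMatrix-class], oriented rows = samples.
#' @export
readMaskedMatrix <- function(path, format = "auto", orientation,
                             labelColumn = FALSE, allowNegative = FALSE) {
  if (missing(orientation))
    stop("'orientation' must be given explicitly: ",
         "\"samples-rows\" or \"samples-cols\"")
  orientation <- match.arg(orientation, c("samples-rows", "samples-cols"))
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop(sprintf("cannot infer format of '%s'; pass 'format'",
                                  path)))
  }
  format <- match.arg(format, c("csv", "tsv", "mtx"))

  labels <- character()
  if (format == "mtx") {
    if (labelColumn) stop("'labelColumn' is not supported for MTX input")
    vals <- as.matrix(Matrix::readMM(path))
  } else {
    df <- utils::read.csv(path, header = TRUE,
                          sep = if (format == "csv") "," else "\t",
                          na.strings = c("", "NA", "NaN", "nan"),
                          check.names = FALSE, colClasses = NA,
                          fill = FALSE)
    if (labelColumn) {
      if (orientation != "samples-rows")
        stop("'labelColumn' requires orientation \"samples-rows\"")
      labels <- as.character(df[[1]])
      df <- df[, -1, drop = FALSE]
    }
    nonNum <- !vapply(df, is.numeric, logical(1))
    if (any(nonNum))
      stop(sprintf("non-numeric data column(s): %s%s",
                   paste(names(df)[nonNum], collapse = ", "),
                   if (!labelColumn)
                     " (did you mean labelColumn = TRUE?)" else ""))
    vals <- as.matrix(df)
    dimnames(vals) <- NULL
  }
  observed <- is.finite(vals)
  if (!allowNegative) {
    neg <- which(observed & vals < 0, arr.ind = TRUE)
    if (nrow(neg))
      stop(sprintf(
        "negative observed value at row %d, column %d (%g); %s",
        neg[1, 1], neg[1, 2], vals[neg[1, 1], neg[1, 2]],
        "non-negative data required (allowNegative = TRUE to override)"))
  }
  if (orientation == "samples-cols") vals <- t(vals)
  MaskedMatrix(vals, is.finite(vals), labels)
}

# Dense matrix -> delimited text with a column-index header, missing as
# empty cells, 12 significant digits (the documented round-trip precision).
.writeDense <- function(vals, path, sep = ",", labels = character()) {
  chr <- matrix("", nrow(vals), ncol(vals))
  ok <- is.finite(vals)
  chr[ok] <- formatC(vals[ok], digits = 12, format = "g")
  header <- paste0("c", seq_len(ncol(vals)))
  if (length(labels)) {
    chr <- cbind(labels, chr)
    header <- c("label", header)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = sep), con)
  writeLines(apply(chr, 1, paste, collapse = sep), con)
  invisible(path)
}

#' Write a masked matrix
#'
#' Inverse of [readMaskedMatrix()]: CSV/TSV with missing entries as empty
#' cells, or MatrixMarket with missing entries stored as `NaN`.  Values
#' are written with 12 significant digits.
#'
#' @param M a [MaskedMatrix-class] (rows = samples).
#' @param path destination file.
#' @param format `"csv"`, `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
writeMaskedMatrix <- function(M, path, format = c("csv", "tsv", "mtx")) {
  format <- match.arg(format)
  vals <- M@values
  vals[!M@observed] <- NA_real_
  if (format == "mtx") {
    if (length(M@labels))
      warning("sample labels are not representable in MTX; dropped")
    vals[!M@observed] <- NaN
    # coordinate triplets written directly: missing entries must be stored
    # as NaN, which Matrix::writeMM cannot emit
    keep <- which(vals != 0 | is.nan(vals))
    ij <- arrayInd(keep, dim(vals))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("%%MatrixMarket matrix coordinate real general",
                 sprintf("%d %d %d", nrow(vals), ncol(vals), length(keep)),
                 sprintf("%d %d %s", ij[, 1], ij[, 2],
                         formatC(vals[keep], digits = 12, format = "g"))),
               con)
  } else {
    .writeDense(vals, path, sep = if (format == "csv") "," else "\t",
                labels = M@labels)
  }
  invisible(path)
}

# Plain key = value sidecar, one entry per line.
.writeKV <- function(kv, path) {
  writeLines(sprintf("%s = %s", names(kv),
                     vapply(kv, function(x) paste(format(x), collapse = " "),
                            character(1))),
             path)
  invisible(path)
}

.configKV <- function(config) {
  list(rank = config@rank, rhoProx = config@rhoProx,
       rhoAug = config@rhoAug, lambda = config@lambda,
       innerTol = config@innerTol, innerMaxIter = config@innerMaxIter,
       outerTol = config@outerTol, outerMaxIter = config@outerMaxIter,
       positivityFloor = config@positivityFloor,
       dualStep = config@dualStep, seed = config@seed)
}

#' Write a robust decomposition to a directory
#'
#' Writes `Y.csv`, `S.csv`, `U.csv`, `V.csv`, `Lambda.csv` (12 significant
#' digits), the per-iteration diagnostics as `history.csv`, and a
#' `metadata.txt` sidecar with run facts and, when given, the solver
#' configuration and seed.
#'
#' @param decomp a [RobustDecomposition-class].
#' @param outdir destination directory (created if needed).
#' @param config optional [SolverConfig-class] to record in the sidecar.
#' @return The directory path, invisibly.
#' @export
writeDecomposition <- function(decomp, outdir, config = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outdir, 2) != 0)
    stop(sprintf("output directory not writable: %s", outdir))
  .writeDense(decomp@Y, file.path(outdir, "Y.csv"))
  .writeDense(decomp@S, file.path(outdir, "S.csv"))
  .writeDense(decomp@factors@U, file.path(outdir, "U.csv"))
  .writeDense(decomp@factors@V, file.path(outdir, "V.csv"))
  .writeDense(decomp@Lambda, file.path(outdir, "Lambda.csv"))
  utils::write.csv(decomp@history, file.path(outdir, "history.csv"),
                   row.names = FALSE)
  kv <- list(class = "RobustDecomposition",
             rows = nrow(decomp@Y), cols = ncol(decomp@Y),
             rank = decomp@factors@rank,
             iterations = decomp@iterations,
             converged = decomp@converged,
             nonzeroS = sum(decomp@S != 0))
  if (!is.null(config)) kv <- c(kv, .configKV(config))
  .writeKV(kv, file.path(outdir, "metadata.txt"))
  invisible(outdir)
}

#' Write a synthetic instance to a directory
#'
#' Writes the corrupted observation (`M.csv` or `M.mtx`), the ground truth
#' (`Mclean.csv`, `Strue.csv`, `U0.csv`, `V0.csv`) and a plain key-value
#' `metadata.txt` recording the full generation provenance.
#'
#' @param inst a [SyntheticInstance-class].
#' @param outdir destination directory (created if needed).
#' @param format `"csv"`, `"tsv"` or `"mtx"` for the observation file.
#' @return The directory path, invisibly.
#' @export
writeInstance <- function(inst, outdir, format = c("csv", "tsv", "mtx")) {
  format <- match.arg(format)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  writeMaskedMatrix(inst@M, file.path(outdir, paste0("M.", format)), format)
  .writeDense(inst@Mclean, file.path(outdir, "Mclean.csv"))
  .writeDense(inst@Strue, file.path(outdir, "Strue.csv"))
  .writeDense(inst@U0, file.path(outdir, "U0.csv"))
  .writeDense(inst@V0, file.path(outdir, "V0.csv"))
  md <- inst@metadata
  kv <- list(d = md$d, n = md$n, r = md$r, seed = md$seed,
             noiseSigma = inst@noiseSigma,
             outliers = sum(inst@Strue != 0),
             missing = prod(dim(inst@Mclean)) - nObserved(inst@M))
  for (i in seq_along(md$steps)) {
    st <- md$steps[[i]]
    kv[[sprintf("step%d", i)]] <-
      paste(vapply(seq_along(st), function(j)
        sprintf("%s=%s", names(st)[j], paste(st[[j]], collapse = ";")),
        character(1)), collapse = " ")
  }
  .writeKV(kv, file.path(outdir, "metadata.txt"))
  invisible(outdir)
}

#' Cluster assignment from factor loadings
#'
#' Labels each sample by its dominant factor: the (1-based) index of the
#' largest entry of its loading row, ties broken toward the smallest
#' index.  Applied to the sample-loading factor of a fit, this is the hard
#' clustering that relates extracted features to sample groups (e.g.
#' tumor stages).
#'
#' @param x a strictly positive loading matrix (rows = samples), or a
#'   [RobustDecomposition-class] / [BregmanNMFFit-class], in which case
#'   the sample-loading factor `factorU()` is used (rows = samples by the
#'   package convention).
#' @return Integer vector of cluster indices in `1..r`.
#' @examples
#' clusterIndex(matrix(c(0.1, 0.9, 0.2, 0.5, 0.5, 0.1), 2, 3, byrow = TRUE))
#' @export
clusterIndex <- function(x) {
  if (is(x, "RobustDecomposition") || is(x, "BregmanNMFFit"))
    x <- factorU(x)
  x <- as.matrix(x)
  if (any(x <= 0)) stop("loadings must be strictly positive")
  max.col(x, ties.method = "first")
}
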