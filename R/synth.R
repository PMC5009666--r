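#' Low-rank non-negative toy instance
#'
#' Draws ground-truth factors with i.i.d. Uniform[0,1] entries and forms
#' the exactly low-rank product \eqn{M = U_0 V_0^t}: the clean,
#' fully observed starting point of every synthetic benchmark.  The
#' default dimensions (50 x 70, rank 8) are the classic small-scale
#' convergence benchmark for this solver family.
#'
#' @param d,n data dimensions (default 50 x 70).
#' @param r ground-truth rank (default 8); must not exceed `min(d, n)`.
#' @param seed integer seed; the instance is bit-reproducible from it.
#' @return A [SyntheticInstance-class] with no corruption: fully observed,
#'   zero outliers, zero noise.
#' @examples
#' makeToy(seed = 1)
#' @export
makeToy <- function(d = 50L, n = 70L, r = 8L, seed = 1L) {
  if (r < 1L || r > min(d, n))
    stop(sprintf("'r' must lie in [1, %d]", min(d, n)))
  set.seed(seed)
  U0 <- matrix(stats::runif(d * r), d, r)
  V0 <- matrix(stats::runif(n * r), n, r)
  Mclean <- U0 %*% t(V0)
  new("SyntheticInstance",
      Mclean = Mclean, U0 = U0, V0 = V0,
      M = MaskedMatrix(Mclean, matrix(TRUE, d, n)),
      Strue = matrix(0, d, n), noiseSigma = 0, seed = as.integer(seed),
      metadata = list(d = as.integer(d), n = as.integer(n),
                      r = as.integer(r), seed = as.integer(seed),
                      steps = list()))
}

# Root-mean-square of the observed entries; the scale to which outlier
# magnitudes and noise levels are relative.
.dataRMS <- function(M) sqrt(mean(M@values[M@observed]^2))

#' Inject sparse outliers
#'
#' Corrupts `ceiling(fraction * d * n)` observed entries with additive
#' spikes of size `magnitude` times the data RMS and random sign,
#' recording them in `Strue`.  Spikes this large (default 10x RMS) are the
#' gross-corruption regime that the sparse term of the robust model is
#' designed to absorb; with random signs, corrupted entries can leave the
#' non-negative range, exactly as gross corruption does in practice.
#'
#' @param inst a [SyntheticInstance-class].
#' @param fraction fraction of entries to corrupt, in \[0, 1\].
#' @param magnitude spike size as a multiple of the data RMS (default 10).
#' @param seed integer seed for positions and signs.
#' @return The corrupted [SyntheticInstance-class]; the previous
#'   observation equals the new one minus `Strue`.
#' @export
injectOutliers <- function(inst, fraction, magnitude = 10,
                           seed = inst@seed + 1L) {
  if (fraction < 0 || fraction > 1) stop("'fraction' must lie in [0, 1]")
  dn <- dim(inst@Mclean)
  npos <- ceiling(fraction * prod(dn))
  if (npos == 0L) return(.recordStep(inst, list(
    op = "outliers", fraction = fraction, magnitude = magnitude,
    seed = as.integer(seed))))
  obsIdx <- which(inst@M@observed)
  if (npos > length(obsIdx))
    stop("more outliers requested than observed entries")
  rms <- .dataRMS(inst@M)
  set.seed(seed)
  pos <- sample(obsIdx, npos)
  spikes <- magnitude * rms * sample(c(-1, 1), npos, replace = TRUE)
  vals <- inst@M@values
  vals[pos] <- vals[pos] + spikes
  Strue <- inst@Strue
  Strue[pos] <- Strue[pos] + spikes
  inst@M <- MaskedMatrix(vals, inst@M@observed, inst@M@labels)
  inst@Strue <- Strue
  .recordStep(inst, list(op = "outliers", fraction = fraction,
                         magnitude = magnitude, seed = as.integer(seed)))
}

#' Mask entries as missing
#'
#' Marks `ceiling(fraction * d * n)` currently observed entries as
#' unobserved, uniformly at random.  Positions in `protect` (linear
#' indices or a two-column row/col matrix) are never masked.  If the draw
#' would leave some row with no observed entry, it is redrawn once; if the
#' second draw also empties a row the instance is kept with a warning (the
#' solver's initialization has a documented global-mean fallback for this
#' case).
#'
#' @param inst a [SyntheticInstance-class].
#' @param fraction fraction of entries to mask, in \[0, 1).
#' @param seed integer seed.
#' @param protect positions that must stay observed (default none).
#' @return The masked [SyntheticInstance-class]; ground truth is retained
#'   for scoring.
#' @export
injectMissing <- function(inst, fraction, seed = inst@seed + 2L,
                          protect = NULL) {
  if (fraction < 0 || fraction >= 1) stop("'fraction' must lie in [0, 1)")
  dn <- dim(inst@Mclean)
  nmask <- ceiling(fraction * prod(dn))
  if (nmask == 0L) return(.recordStep(inst, list(
    op = "missing", fraction = fraction, seed = as.integer(seed))))
  protIdx <- integer(0)
  if (!is.null(protect)) {
    protIdx <- if (is.matrix(protect))
      protect[, 1] + (protect[, 2] - 1L) * dn[1] else as.integer(protect)
  }
  candidates <- setdiff(which(inst@M@observed), protIdx)
  if (nmask > length(candidates))
    stop("cannot mask more entries than are observed and unprotected")
  set.seed(seed)
  pick <- sample(candidates, nmask)
  observed <- inst@M@observed
  observed[pick] <- FALSE
  if (any(rowSums(observed) == 0L)) {
    pick <- sample(candidates, nmask)  # one resample
    observed <- inst@M@observed
    observed[pick] <- FALSE
    if (any(rowSums(observed) == 0L))
      warning("masking left at least one row with no observed entries")
  }
  vals <- inst@M@values
  vals[pick] <- NA_real_
  inst@M <- MaskedMatrix(vals, observed, inst@M@labels)
  .recordStep(inst, list(op = "missing", fraction = fraction,
                         seed = as.integer(seed), protect = protIdx))
}

#' Add dense observation noise
#'
#' Adds i.i.d. centered Gaussian noise with standard deviation
#' `sigma` times the data RMS to every observed entry, then clips at zero
#' those entries that were non-negative before the noise (clipping an
#' injected negative outlier would silently erase it).  The number of
#' clipped entries is recorded in the metadata.
#'
#' @param inst a [SyntheticInstance-class].
#' @param sigma relative noise level (>= 0); 0 is the identity.
#' @param seed integer seed.
#' @return The noisy [SyntheticInstance-class].
#' @export
addNoise <- function(inst, sigma, seed = inst@seed + 3L) {
  if (sigma < 0) stop("'sigma' must be non-negative")
  if (sigma == 0) return(.recordStep(inst, list(
    op = "noise", sigma = 0, seed = as.integer(seed), clipped = 0L)))
  obsIdx <- which(inst@M@observed)
  rms <- .dataRMS(inst@M)
  set.seed(seed)
  noise <- stats::rnorm(length(obsIdx), mean = 0, sd = sigma * rms)
  vals <- inst@M@values
  before <- vals[obsIdx]
  after <- before + noise
  clip <- after < 0 & before >= 0
  after[clip] <- 0
  vals[obsIdx] <- after
  inst@M <- MaskedMatrix(vals, inst@M@observed, inst@M@labels)
  inst@noiseSigma <- sigma
  .recordStep(inst, list(op = "noise", sigma = sigma,
                         seed = as.integer(seed),
                         clipped = as.integer(sum(clip))))
}

.recordStep <- function(inst, step) {
  inst@metadata$steps <- c(inst@metadata$steps, list(step))
  inst
}

#' Regenerate an instance from its metadata
#'
#' Replays the base draw and every recorded corruption step, yielding a
#' bit-identical copy of the instance — the provenance contract of the
#' generator.  The canonical corruption order is outliers, then
#' missingness, then noise; the metadata records the order actually used.
#'
#' @param metadata the `metadata` list of a [SyntheticInstance-class].
#' @return The regenerated [SyntheticInstance-class].
#' @export
regenerateInstance <- function(metadata) {
  inst <- makeToy(metadata$d, metadata$n, metadata$r, metadata$seed)
  for (step in metadata$steps) {
    inst <- switch(step$op,
      outliers = injectOutliers(inst, step$fraction, step$magnitude,
                                step$seed),
      missing = injectMissing(inst, step$fraction, step$seed,
                              protect = step$protect),
      noise = addNoise(inst, step$sigma, step$seed),
      stop(sprintf("unknown generation step '%s'", step$op)))
  }
  inst
}
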