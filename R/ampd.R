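# Automatic multiscale-based peak detection (AMPD) for quasi-periodic
# physiological signals. The detector builds a local-maxima scalogram over
# scales k = 1..L (L = ceiling(N/2) - 1), selects the dominant scale lambda
# as the argmin of the scalogram row sums, and reports the samples that are
# local maxima at every scale up to lambda. Troughs are peaks of the negated
# signal. All steps are deterministic: the non-maximum scalogram entries use
# the fixed constant 1.5 (the expectation of the random fill 1 + U(0,1) used
# historically) because only the zero/non-zero pattern matters.

.ampdFill <- 1.5

#' Remove the least-squares straight line from a signal
#'
#' Standard preprocessing for the multiscale peak detector: subtracts the
#' least-squares linear fit so that slow monotone drift does not bias the
#' local-maxima scalogram.
#'
#' @param signal a numeric vector or a [Trace-class] (at least 2 samples).
#' @return The detrended signal, same type as the input; its mean is zero to
#'   numerical precision.
#' @examples
#' detrendLinear(c(1, 3, 5, 7, 9))   # an exact line -> all zeros
#' detrendLinear(c(0, 1, 0))         # -> c(-1/3, 2/3, -1/3)
#' @export
detrendLinear <- function(signal) {
  x <- asTraceValues(signal)
  n <- length(x)
  if (n < 2) stopInvalid("detrendLinear needs at least 2 samples")
  if (!all(is.finite(x))) stopInvalid("signal must be finite")
  t <- seq_len(n) - (n + 1) / 2           # centred time axis
  b <- sum(t * x) / sum(t * t)
  r <- x - mean(x) - b * t
  if (is(signal, "Trace")) Trace(r, signal@sampleRate, signal@t0) else r
}

#' Local-maxima scalogram
#'
#' Builds the L-by-N matrix M underlying the multiscale detector:
#' \code{M[k, i] = 0} when both neighbours at lag k exist and
#' \code{x[i] > x[i - k]} and \code{x[i] > x[i + k]}; all other entries hold
#' the deterministic constant 1.5. The maximum scale is
#' \code{L = ceiling(N/2) - 1}. Row k can contain at most \code{N - 2k} zeros.
#'
#' The input is normally the linearly detrended signal (see
#' [detrendLinear()]).
#'
#' @param x numeric vector or [Trace-class], at least 10 samples.
#' @return Numeric matrix of dimension \code{L x N}.
#' @seealso [selectScale()], [findPeaksAMPD()]
#' @export
localMaximaScalogram <- function(x) {
  x <- asTraceValues(x)
  n <- length(x)
  if (n < 10) stopInvalid("localMaximaScalogram needs at least 10 samples")
  if (!all(is.finite(x))) stopInvalid("signal must be finite")
  L <- as.integer(ceiling(n / 2) - 1)
  M <- matrix(.ampdFill, nrow = L, ncol = n)
  for (k in seq_len(L)) {
    i <- (k + 1L):(n - k)
    hit <- x[i] > x[i - k] & x[i] > x[i + k]
    M[k, i[hit]] <- 0
  }
  M
}

#' Select the dominant scale of a scalogram
#'
#' Sums each row of the local-maxima scalogram (\code{gamma[k]}) and selects
#' the scale minimizing the sum; ties break toward the smallest k (the finest
#' scale consistent with the minimum).
#'
#' @param M matrix from [localMaximaScalogram()].
#' @return A [ScaleSelection-class] with slots \code{gamma}, \code{lambda},
#'   \code{L}.
#' @export
selectScale <- function(M) {
  if (!is.matrix(M) || nrow(M) < 1 || ncol(M) < 1)
    stopInvalid("selectScale needs a non-empty matrix")
  gamma <- rowSums(M)
  new("ScaleSelection", gamma = gamma, lambda = which.min(gamma),
      L = nrow(M))
}

# Shared peak-finding core. Works on the detrended values; returns indices.
#
# A sample i is reported when it is a local maximum at every scale
# k = 1..lambda. Comparisons use x[i] > x[i - k] and x[i] >= x[i + k]; the
# non-strict right comparison resolves tied plateaus (common on
# integer-quantized diameter traces) to their leftmost sample and is
# identical to the strict rule on tie-free signals. At scales whose
# neighbour falls outside the record the comparison is vacuously satisfied,
# except at k = 1 which always requires both neighbours, so the contract of a
# reported peak as a strict k = 1 local maximum holds for all interior
# detections.
#
# The final sample (i = N) is additionally admitted when it dominates every
# in-range lag AND the last three steps contain a strict downward reversal.
# Smooth noiseless signals approach the boundary monotonically over those
# steps, so the final sample is never reported there (matching a
# brute-force interior local-maxima scan); on noisy plateaus whose running
# maximum happens to fall on the last sample, the event is still counted.
# The first sample is never reported: a recording that opens high cannot be
# distinguished from the tail of an extremum that occurred before
# acquisition started, whereas a trailing extremum has its rise on record.
.findPeaksCore <- function(xd, rawRange) {
  n <- length(xd)
  L <- as.integer(ceiling(n / 2) - 1)
  # a signal that is flat after detrending (constant or exact line) has no
  # peaks; without this floor, floating-point dust in the residuals would be
  # scanned for "maxima"
  if (diff(range(xd)) <= 1e-12 * max(1, rawRange))
    return(list(indices = integer(0),
                scale = new("ScaleSelection", gamma = rep(.ampdFill * n, L),
                            lambda = 1L, L = L)))
  # gamma over the strict both-neighbour scalogram, without materializing M
  z <- integer(L)
  for (k in seq_len(L)) {
    i <- (k + 1L):(n - k)
    z[k] <- sum(xd[i] > xd[i - k] & xd[i] > xd[i + k])
  }
  gamma <- .ampdFill * (n - z)
  lambda <- which.min(gamma)            # first minimum = smallest k
  sel <- new("ScaleSelection", gamma = gamma, lambda = lambda, L = L)

  cand <- logical(n)
  cand[2:(n - 1)] <- xd[2:(n - 1)] > xd[1:(n - 2)] & xd[2:(n - 1)] >= xd[3:n]
  if (lambda >= 2L) {
    for (k in 2:lambda) {
      if (!any(cand)) break
      left <- rep(TRUE, n)
      left[(k + 1L):n] <- xd[(k + 1L):n] > xd[1:(n - k)]
      right <- rep(TRUE, n)
      right[1:(n - k)] <- xd[1:(n - k)] >= xd[(k + 1L):n]
      cand <- cand & left & right
    }
  }
  # guarded admission of the final sample: it must dominate every in-range
  # lag AND show a strict downward reversal within the last 3 steps. Smooth
  # noiseless signals approach the boundary monotonically over those steps
  # (even when a turning point lies further back), so this never fires
  # there; on a noisy plateau whose running maximum lands on the last
  # sample, the immediate reversals admit the event. The tolerance keeps
  # floating-point dust from counting as a reversal.
  w <- min(lambda, n - 1L)
  g <- min(3L, w)
  tol <- 1e-9 * diff(range(xd))
  if (all(xd[n] > xd[n - seq_len(w)]) &&
      any(diff(xd[(n - g):n]) < -tol))
    cand[n] <- TRUE

  list(indices = which(cand), scale = sel)
}

#' Find peaks with the automatic multiscale-based detector
#'
#' Detrends the signal (see [detrendLinear()]), computes the scalogram row
#' sums, selects the dominant scale lambda, and reports every sample that is
#' a local maximum at all scales up to lambda. Returned indices refer to the
#' original (undetrended) signal, 1-based. A flat signal yields an empty
#' index set.
#'
#' @param signal numeric vector or [Trace-class], at least 10 samples.
#' @return A list with \code{indices} (sorted integer vector) and
#'   \code{scale} (a [ScaleSelection-class]).
#' @examples
#' x <- sin(2 * pi * (0:199) / 24)
#' findPeaksAMPD(x)$indices    # 9 peaks: samples 7, 31, ..., 199
#' @export
findPeaksAMPD <- function(signal) {
  x <- asTraceValues(signal)
  n <- length(x)
  if (n < 10) stopInvalid("findPeaksAMPD needs at least 10 samples")
  if (!all(is.finite(x))) stopInvalid("signal must be finite")
  .findPeaksCore(as.numeric(detrendLinear(x)), diff(range(x)))
}

#' Detect peaks and troughs of a contractility trace
#'
#' Runs [findPeaksAMPD()] on the signal for peaks and on the negated signal
#' for troughs (each pass detrends independently), then enforces strict
#' peak/trough alternation with [enforceAlternation()].
#'
#' @param signal numeric vector or [Trace-class], at least 10 samples.
#' @return A [PeakTroughSet-class].
#' @examples
#' x <- 100 + 10 * sin(2 * pi * (0:199) / 24)
#' detectPeaksTroughs(x)
#' @export
detectPeaksTroughs <- function(signal) {
  x <- asTraceValues(signal)
  p <- findPeaksAMPD(x)
  t <- findPeaksAMPD(-x)
  alt <- enforceAlternation(p$indices, t$indices, x)
  new("PeakTroughSet", peaks = as.integer(alt$peaks),
      troughs = as.integer(alt$troughs),
      scalePeaks = p$scale, scaleTroughs = t$scale, n = length(x))
}

#' Enforce strict peak/trough alternation
#'
#' Merges the two event lists in time order; wherever two or more events of
#' the same type are adjacent, only the most extreme one is kept (largest
#' signal value for peaks, smallest for troughs; ties keep the earliest).
#' The surviving events strictly interleave. Needed so that each peak can be
#' paired with the immediately following trough when measuring per-cycle
#' amplitudes.
#'
#' @param peaks,troughs sorted integer index vectors.
#' @param x the signal values the indices refer to.
#' @return A list with the pruned \code{peaks} and \code{troughs} vectors.
#' @examples
#' x <- c(rep(0, 9), 5, rep(0, 9), 7, rep(0, 9), -2, rep(0, 19), 3, 0)
#' enforceAlternation(c(10, 20, 50), c(30), x)  # drops the weaker peak at 10
#' @export
enforceAlternation <- function(peaks, troughs, x) {
  x <- asTraceValues(x)
  peaks <- as.integer(peaks); troughs <- as.integer(troughs)
  if (length(peaks) == 0 || length(troughs) == 0)
    return(list(peaks = peaks, troughs = troughs))
  idx <- c(peaks, troughs)
  if (min(idx) < 1 || max(idx) > length(x))
    stopInvalid("event indices out of range")
  type <- rep(c(1L, 2L), c(length(peaks), length(troughs)))  # 1 peak, 2 trough
  o <- order(idx)
  idx <- idx[o]; type <- type[o]
  runs <- rle(type)
  keep <- integer(0)
  pos <- 0L
  for (j in seq_along(runs$lengths)) {
    member <- (pos + 1L):(pos + runs$lengths[j])
    pos <- pos + runs$lengths[j]
    if (length(member) == 1L) { keep <- c(keep, member); next }
    v <- x[idx[member]]
    best <- if (runs$values[j] == 1L) member[which.max(v)] else
      member[which.min(v)]
    keep <- c(keep, best)
  }
  keep <- sort(keep)
  list(peaks = idx[keep[type[keep] == 1L]],
       troughs = idx[keep[type[keep] == 2L]])
}
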