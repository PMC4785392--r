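# Contractility outcome measures: instantaneous mean, per-cycle amplitudes,
# contraction frequency, percent amplitude, pumping score, tone, and
# baseline-normalized treatment effects.

#' Instantaneous mean of a contractility trace
#'
#' Centred moving average against which per-cycle amplitudes are expressed.
#' The window is \code{roundToOdd(1.5 * median inter-peak interval)} samples,
#' so it spans roughly one and a half contraction cycles and follows slow
#' tonic drift while averaging out the phasic oscillation. Half-window
#' regions at both ends are flagged as excluded: there the average is
#' computed from a truncated window and cycles falling inside them are not
#' quantified (the detector also needs these margins to calibrate, so they
#' appear shaded in typical algorithm output).
#'
#' @param trace a [Trace-class] or numeric vector.
#' @param events a [PeakTroughSet-class] for the same trace (at least 2
#'   peaks are required to estimate the cycle length).
#' @return A list with \code{values} (numeric, same length as the trace),
#'   \code{excluded} (logical, TRUE in the edge calibration regions) and
#'   \code{window} (the window width in samples).
#' @export
instantaneousMean <- function(trace, events) {
  x <- asTraceValues(trace)
  if (!all(is.finite(x))) stopInvalid("trace must be finite")
  pk <- if (is(events, "PeakTroughSet")) events@peaks else as.integer(events)
  if (length(pk) < 2)
    stopInvalid("instantaneousMean needs at least 2 peaks to estimate a period")
  W <- roundToOdd(1.5 * stats::median(diff(pk)))
  n <- length(x)
  h <- W %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  vals <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  excluded <- seq_len(n) <= h | seq_len(n) > n - h
  list(values = vals, excluded = excluded, window = W)
}

# Least-squares quadratic apex readout around a detected extremum: fits a
# parabola to the samples within +-h of index i and evaluates it at its
# stationary point (clamped to the window). Unlike reading the raw sample,
# this does not inherit the upward bias of having selected the largest noisy
# sample in the neighbourhood. Suited to broad, well-resolved extrema.
.apexValue <- function(x, i, h, what = c("max", "min")) {
  what <- match.arg(what)
  j <- max(1L, i - h):min(length(x), i + h)
  if (length(j) < 4L) return(x[i])
  d <- j - i
  fit <- stats::lm.fit(cbind(1, d, d * d), x[j])
  b <- fit$coefficients
  if (!is.finite(b[3]) || abs(b[3]) < 1e-12) return(mean(x[j]))
  apex <- -b[2] / (2 * b[3])
  apex <- max(-h, min(h, apex))
  val <- b[1] + b[2] * apex + b[3] * apex^2
  # never extrapolate past the observed extremum in the wrong direction
  if (what == "max") min(val, max(x[j])) else max(val, min(x[j]))
}

# Three-point parabolic sub-sample interpolation through (i-1, i, i+1):
# recovers part of the between-samples nadir/apex of a sharp, marginally
# resolved extremum (classic sub-sample peak interpolation).
.interp3 <- function(x, i) {
  if (i <= 1L || i >= length(x)) return(x[i])
  y0 <- x[i - 1]; y1 <- x[i]; y2 <- x[i + 1]
  den <- y0 - 2 * y1 + y2
  if (!is.finite(den) || abs(den) < 1e-12) return(y1)
  d <- max(-1, min(1, 0.5 * (y0 - y2) / den))
  y1 - 0.25 * (y0 - y2) * d
}

#' Measure individual contraction cycles
#'
#' Pairs every peak with the immediately following trough in the alternating
#' event sequence and computes the per-cycle amplitude as percent of the
#' instantaneous mean evaluated at the midpoint sample between peak and
#' trough. Cycles whose peak or trough falls in an excluded edge region are
#' dropped.
#'
#' The default \code{valueMethod = "apex"} readout matches the morphology of
#' CLV contractility traces: peak (end-diastolic) values come from a local
#' least-squares quadratic apex fit (window half-width about 1/12 cycle,
#' minimum 2 samples), which removes the upward selection bias of reading
#' the largest noisy sample on a broad diastolic maximum; trough
#' (contraction nadir) values come from a three-point parabolic sub-sample
#' interpolation, which recovers part of the nadir that falls between
#' samples of a sharp constriction. \code{valueMethod = "raw"} reads the raw
#' samples at the detected indices.
#'
#' @param trace a [Trace-class] or numeric vector.
#' @param events a [PeakTroughSet-class] (alternation already enforced).
#' @param instMean result of [instantaneousMean()]; pass NULL to compute it
#'   (or to fall back to the whole-trace mean with no exclusions when fewer
#'   than 2 peaks exist).
#' @param valueMethod \code{"apex"} (default) or \code{"raw"}.
#' @return A data.frame with one row per cycle: \code{cycle},
#'   \code{peak_index}, \code{trough_index}, \code{peak_value},
#'   \code{trough_value}, \code{local_mean}, \code{pct_amplitude}.
#' @export
measureCycles <- function(trace, events, instMean = NULL,
                          valueMethod = c("apex", "raw")) {
  valueMethod <- match.arg(valueMethod)
  x <- asTraceValues(trace)
  stopifnot(is(events, "PeakTroughSet"))
  pk <- events@peaks; tr <- events@troughs
  empty <- data.frame(cycle = integer(0), peak_index = integer(0),
                      trough_index = integer(0), peak_value = numeric(0),
                      trough_value = numeric(0), local_mean = numeric(0),
                      pct_amplitude = numeric(0))
  if (length(pk) == 0 || length(tr) == 0) return(empty)
  if (is.null(instMean)) {
    instMean <- if (length(pk) >= 2) instantaneousMean(x, events) else
      list(values = rep(mean(x), length(x)),
           excluded = rep(FALSE, length(x)), window = NA_integer_)
  }
  period <- if (length(pk) >= 2) stats::median(diff(pk)) else length(x)
  h <- max(2L, as.integer(round(period / 12)))
  rows <- vector("list", length(pk))
  ci <- 0L
  for (p in pk) {
    nxt <- tr[tr > p]
    if (length(nxt) == 0) break
    t1 <- nxt[1]
    if (instMean$excluded[p] || instMean$excluded[t1]) next
    mid <- (p + t1) %/% 2L
    lm0 <- instMean$values[mid]
    if (!is.finite(lm0) || lm0 <= 0) next
    pv <- if (valueMethod == "raw") x[p] else .apexValue(x, p, h, "max")
    tv <- if (valueMethod == "raw") x[t1] else -.interp3(-x, t1)
    ci <- ci + 1L
    rows[[ci]] <- data.frame(cycle = ci, peak_index = p, trough_index = t1,
                             peak_value = pv, trough_value = tv,
                             local_mean = lm0,
                             pct_amplitude = 100 * (pv - tv) / lm0)
  }
  if (ci == 0L) return(empty)
  do.call(rbind, rows[seq_len(ci)])
}

#' Contraction frequency
#'
#' Number of detected peaks inside the window divided by the window duration
#' in minutes. Peaks in the edge calibration regions are included: counting
#' needs no local mean, and short windows would otherwise lose events.
#'
#' @param events a [PeakTroughSet-class] or integer vector of peak indices.
#' @param duration window duration in seconds (positive).
#' @return Contractions per minute.
#' @examples
#' contractionFrequency(seq(1, 450, by = 25), 180)  # 18 peaks in 3 min -> 6
#' @export
contractionFrequency <- function(events, duration) {
  if (!is.finite(duration) || duration <= 0)
    stopInvalid("window duration must be positive")
  np <- if (is(events, "PeakTroughSet")) length(events@peaks) else
    length(events)
  np / (duration / 60)
}

#' Mean percent amplitude over cycles
#'
#' Arithmetic mean of the per-cycle percent amplitudes from
#' [measureCycles()]. An empty cycle table yields NA (undefined), the
#' quiescent-vessel convention.
#'
#' @param cycles data.frame from [measureCycles()].
#' @return Percent of instantaneous mean, or NA.
#' @export
percentAmplitude <- function(cycles) {
  if (is.null(cycles) || nrow(cycles) == 0) return(NA_real_)
  mean(cycles$pct_amplitude)
}

#' Pumping score
#'
#' The phasic pumping-efficiency measure: contraction frequency (per minute)
#' times percent amplitude, exactly. Quiescent convention: with frequency 0
#' the score is 0 even though the amplitude is undefined; with positive
#' frequency and undefined amplitude the score is undefined (NA).
#'
#' @param x frequency in contractions per minute (or, via the method for
#'   [ContractilitySummary-class], a summary whose stored score is returned).
#' @param pctAmplitude percent amplitude (may be NA).
#' @return The score, in (1/min) x percent.
#' @examples
#' pumpingScore(6.5, 40)   # 260
#' pumpingScore(0, NA)     # 0, quiescent vessel
#' @export
setMethod("pumpingScore", "numeric", function(x, pctAmplitude) {
  if (!is.finite(x) || x < 0) stopInvalid("frequency must be non-negative")
  if (x == 0) return(0)
  x * pctAmplitude
})

#' Tonic change between two traces
#'
#' Vessel tone quantified as the mean signal level of the post-treatment
#' trace as percent of the pre-treatment mean. Values below 100% indicate
#' constriction (a constricted vessel holds less tracer, so its mean
#' fluorescence drops).
#'
#' @param pre,post [Trace-class] objects or numeric vectors.
#' @return Percent of the pre-treatment mean.
#' @examples
#' toneChange(rep(1000, 20), rep(656, 20))   # 65.6
#' @export
toneChange <- function(pre, post) {
  a <- asTraceValues(pre); b <- asTraceValues(post)
  if (length(a) == 0 || length(b) == 0) stopInvalid("traces must be non-empty")
  m <- mean(a)
  if (!is.finite(m) || m <= 0)
    stopInvalid("pre-treatment mean must be positive")
  100 * mean(b) / m
}

#' Pearson correlation between two traces
#'
#' Product-moment correlation, used to compare diameter and fluorescence
#' readouts of the same vessel. Thin wrapper over [stats::cor()] with the
#' input checks the pipeline needs.
#'
#' @param a,b equal-length numeric vectors or [Trace-class] objects
#'   (length at least 3, both with non-zero variance).
#' @return r in \[-1, 1\].
#' @export
pearsonCorrelation <- function(a, b) {
  a <- asTraceValues(a); b <- asTraceValues(b)
  if (length(a) != length(b)) stopInvalid("traces must have equal length")
  if (length(a) < 3) stopInvalid("need at least 3 paired samples")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stopInvalid("zero variance input")
  stats::cor(a, b)
}

#' Deviation statistics between automated and manual measurements
#'
#' @param auto,manual equal-length numeric vectors.
#' @return A list with \code{mad} (mean absolute deviation) and \code{rmsd}
#'   (root mean square deviation), in the input units; \code{rmsd >= mad}
#'   always.
#' @examples
#' deviationStats(c(1, 2, 3), c(2, 2, 5))  # mad 1, rmsd sqrt(5/3)
#' @export
deviationStats <- function(auto, manual) {
  auto <- asTraceValues(auto); manual <- asTraceValues(manual)
  if (length(auto) != length(manual) || length(auto) < 1)
    stopInvalid("inputs must be non-empty vectors of equal length")
  d <- auto - manual
  list(mad = mean(abs(d)), rmsd = sqrt(mean(d^2)))
}

#' Summarize contractility of a trace over a window
#'
#' The full per-trace pipeline: window the trace, detect peaks and troughs,
#' enforce alternation, compute the instantaneous mean, measure cycles, and
#' assemble frequency, percent amplitude, pumping score and mean level into
#' a [ContractilitySummary-class]. With fewer than 2 peaks the instantaneous
#' mean falls back to the whole-window mean and no edge regions are
#' excluded.
#'
#' @param trace a [Trace-class].
#' @param window numeric (start, end) in seconds on the trace's clock;
#'   default the full trace extent. Samples with \code{start <= t < end}
#'   are analyzed.
#' @param valueMethod extremum readout, see [measureCycles()].
#' @param amplitudeMethod \code{"per-cycle"} (default) averages per-cycle
#'   percent ratios; \code{"global"} divides the mean raw peak-trough
#'   difference by the window mean instead.
#' @return A [ContractilitySummary-class].
#' @examples
#' tr <- Trace(100 + 15 * sin(2 * pi * (0:449) / 25), sampleRate = 2.5)
#' summarizeTrace(tr)
#' @export
summarizeTrace <- function(trace, window = NULL,
                           valueMethod = c("apex", "raw"),
                           amplitudeMethod = c("per-cycle", "global")) {
  valueMethod <- match.arg(valueMethod)
  amplitudeMethod <- match.arg(amplitudeMethod)
  stopifnot(is(trace, "Trace"))
  tt <- traceTimes(trace)
  if (is.null(window))
    window <- c(tt[1], tt[length(tt)] + 1 / trace@sampleRate)
  wtr <- windowTrace(trace, window[1], window[2])
  x <- wtr@values
  dur <- window[2] - window[1]
  ev <- detectPeaksTroughs(x)
  im <- if (length(ev@peaks) >= 2) instantaneousMean(x, ev) else
    list(values = rep(mean(x), length(x)),
         excluded = rep(FALSE, length(x)), window = NA_integer_)
  cyc <- measureCycles(x, ev, im, valueMethod = valueMethod)
  freq <- contractionFrequency(ev, dur)
  amp <- if (amplitudeMethod == "per-cycle") percentAmplitude(cyc) else {
    if (nrow(cyc) == 0) NA_real_ else
      100 * mean(cyc$peak_value - cyc$trough_value) / mean(x)
  }
  score <- if (freq == 0) 0 else freq * amp
  # cycle indices -> times for the report
  if (nrow(cyc)) {
    cyc$peak_t <- wtr@t0 + (cyc$peak_index - 1) / wtr@sampleRate
    cyc$trough_t <- wtr@t0 + (cyc$trough_index - 1) / wtr@sampleRate
  } else {
    cyc$peak_t <- numeric(0); cyc$trough_t <- numeric(0)
  }
  new("ContractilitySummary", frequency = freq, pctAmplitude = amp,
      pumpingScore = score, meanLevel = mean(x),
      nCycles = nrow(cyc), window = as.numeric(window), cycles = cyc)
}

#' Normalize a post-treatment summary to its baseline
#'
#' Expresses each post-treatment metric as percent of the baseline metric,
#' the baseline being normalized to 100%. Tone is the ratio of window mean
#' levels. A zero or undefined baseline metric flags that ratio as NA while
#' the others are still computed.
#'
#' @param baseline,post [ContractilitySummary-class] objects, typically from
#'   the 0-2 min baseline and 3-6 min post-treatment windows of an 8-min
#'   recording with treatment at t = 2 min.
#' @return A [TreatmentEffect-class].
#' @export
normalizeToBaseline <- function(baseline, post) {
  stopifnot(is(baseline, "ContractilitySummary"),
            is(post, "ContractilitySummary"))
  ratio <- function(b, p) {
    if (!is.finite(b) || b <= 0 || !is.finite(p)) NA_real_ else 100 * p / b
  }
  pct <- c(frequency = ratio(baseline@frequency, post@frequency),
           amplitude = ratio(baseline@pctAmplitude, post@pctAmplitude),
           pumping = ratio(baseline@pumpingScore, post@pumpingScore),
           tone = ratio(baseline@meanLevel, post@meanLevel))
  new("TreatmentEffect", baseline = baseline, post = post, percents = pct)
}

#' Analyze a treatment recording
#'
#' Convenience wrapper for the two-window treatment design: summarizes the
#' trace over the baseline and post-treatment windows and normalizes post to
#' baseline. Defaults follow the 8-min design with treatment at t = 2 min:
#' baseline 0-2 min, post 3-6 min.
#'
#' @param trace a [Trace-class] (e.g. the vessel MFI trace).
#' @param baselineWindow,postWindow numeric (start, end) seconds.
#' @param ... passed to [summarizeTrace()].
#' @return A [TreatmentEffect-class].
#' @export
analyzeTreatment <- function(trace, baselineWindow = c(0, 120),
                             postWindow = c(180, 360), ...) {
  b <- summarizeTrace(trace, baselineWindow, ...)
  p <- summarizeTrace(trace, postWindow, ...)
  normalizeToBaseline(b, p)
}
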