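#' @import methods
NULL

#' Uniformly sampled physiological signal
#'
#' A \code{Trace} holds a uniformly sampled 1-D signal — an inner-diameter
#' time course in micrometres or a mean fluorescence intensity (MFI) time
#' course in camera units — together with its sampling rate and time origin.
#' All detection and quantification functions in the package consume traces.
#'
#' @slot values numeric vector of samples (finite; at least 10 samples).
#' @slot sampleRate samples per second (finite, positive).
#' @slot t0 time of the first sample in seconds.
#'
#' @seealso [Trace()] for the constructor, [detectPeaksTroughs()],
#'   [summarizeTrace()]
#' @export
setClass("Trace",
  representation(values = "numeric", sampleRate = "numeric", t0 = "numeric"),
  prototype(values = numeric(0), sampleRate = 1, t0 = 0)
)

setValidity("Trace", function(object) {
  msg <- character(0)
  if (length(object@values) < 10)
    msg <- c(msg, "a Trace needs at least 10 samples")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "all trace values must be finite")
  if (length(object@sampleRate) != 1 || !is.finite(object@sampleRate) ||
      object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single finite positive number")
  if (length(object@t0) != 1 || !is.finite(object@t0))
    msg <- c(msg, "t0 must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Construct a Trace
#'
#' @param values numeric vector of samples.
#' @param sampleRate sampling rate in samples per second.
#' @param t0 time of the first sample in seconds (default 0).
#' @return A [Trace-class] object.
#' @examples
#' tr <- Trace(100 + 10 * sin(2 * pi * (0:449) / 25), sampleRate = 2.5)
#' tr
#' @export
Trace <- function(values, sampleRate, t0 = 0) {
  new("Trace", values = as.numeric(values),
      sampleRate = as.numeric(sampleRate), t0 = as.numeric(t0))
}

#' Multiscale scale selection diagnostics
#'
#' Records, for one AMPD run, the row sums \code{gamma[k]} of the local-maxima
#' scalogram over scales \code{k = 1..L} and the selected scale
#' \code{lambda} (the smallest k attaining the minimum of gamma).
#'
#' @slot gamma numeric vector of scalogram row sums, one per scale.
#' @slot lambda selected scale (integer in 1..L).
#' @slot L maximum scale, \code{ceiling(N/2) - 1}.
#' @export
setClass("ScaleSelection",
  representation(gamma = "numeric", lambda = "integer", L = "integer"),
  prototype(gamma = NA_real_, lambda = 1L, L = 1L)
)

setValidity("ScaleSelection", function(object) {
  if (object@lambda < 1L || object@lambda > object@L)
    return("lambda must lie in 1..L")
  if (length(object@gamma) != object@L)
    return("gamma must have one entry per scale")
  TRUE
})

#' Detected peaks and troughs of a contractility trace
#'
#' Indices (1-based, on the original undetrended trace) of the detected
#' peaks and troughs, plus the per-run scale-selection diagnostics. After
#' [enforceAlternation()] peaks and troughs strictly interleave.
#'
#' @slot peaks sorted integer vector of peak sample indices.
#' @slot troughs sorted integer vector of trough sample indices.
#' @slot scalePeaks [ScaleSelection-class] for the peak pass.
#' @slot scaleTroughs [ScaleSelection-class] for the trough pass.
#' @slot n number of samples in the analyzed trace.
#' @export
setClass("PeakTroughSet",
  representation(peaks = "integer", troughs = "integer",
                 scalePeaks = "ScaleSelection", scaleTroughs = "ScaleSelection",
                 n = "integer")
)

setValidity("PeakTroughSet", function(object) {
  msg <- character(0)
  idx <- c(object@peaks, object@troughs)
  if (length(idx) && (min(idx) < 1L || max(idx) > object@n))
    msg <- c(msg, "indices must lie within the trace")
  if (is.unsorted(object@peaks, strictly = TRUE) && length(object@peaks) > 1)
    msg <- c(msg, "peaks must be strictly sorted")
  if (is.unsorted(object@troughs, strictly = TRUE) && length(object@troughs) > 1)
    msg <- c(msg, "troughs must be strictly sorted")
  if (anyDuplicated(idx))
    msg <- c(msg, "peak and trough indices must be distinct")
  if (length(msg)) msg else TRUE
})

#' Vessel measurement geometry
#'
#' Defines the regions used by the diameter-tracking algorithm, mirroring how
#' an analyst draws them on the first frame: a circular ROI of radius
#' \code{r} centred on the vessel, a background ROI of radius \code{0.5 r}
#' whose centre lies at \code{center + 2 r * normal}, and a measurement line
#' of length \code{3 r} running from the background-ROI centre through the
#' vessel centre to the far edge of the vessel ROI (\code{center - r * normal}).
#'
#' Coordinates are 1-based pixel centres, x rightward (column), y downward
#' (row); \code{normal} must be a unit vector perpendicular to the vessel axis.
#'
#' @slot center numeric length-2, (x, y) of the vessel-centre point in pixels.
#' @slot normal numeric length-2 unit vector perpendicular to the vessel axis.
#' @slot r vessel ROI radius in pixels (at least 3).
#' @slot scale micrometres per pixel (positive).
#' @export
setClass("VesselGeometry",
  representation(center = "numeric", normal = "numeric",
                 r = "numeric", scale = "numeric")
)

setValidity("VesselGeometry", function(object) {
  msg <- character(0)
  if (length(object@center) != 2 || !all(is.finite(object@center)))
    msg <- c(msg, "center must be finite (x, y)")
  if (length(object@normal) != 2 || !all(is.finite(object@normal)) ||
      abs(sqrt(sum(object@normal^2)) - 1) > 1e-6)
    msg <- c(msg, "normal must be a unit vector")
  if (length(object@r) != 1 || !is.finite(object@r) || object@r < 3)
    msg <- c(msg, "r must be at least 3 pixels")
  if (length(object@scale) != 1 || !is.finite(object@scale) ||
      object@scale <= 0)
    msg <- c(msg, "scale (um/pixel) must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a VesselGeometry
#'
#' @param center (x, y) vessel-centre point in pixels (1-based pixel centres).
#' @param normal length-2 vector perpendicular to the vessel axis; it is
#'   normalized to unit length. Alternatively give \code{angle} instead.
#' @param r vessel ROI radius in pixels.
#' @param scale micrometres per pixel.
#' @param angle optional angle of the normal in degrees (0 = +x, 90 = +y);
#'   used when \code{normal} is missing.
#' @return A [VesselGeometry-class] object.
#' @examples
#' vesselGeometry(center = c(32, 308), angle = -90, r = 100, scale = 2)
#' @export
vesselGeometry <- function(center, normal = NULL, r, scale, angle = NULL) {
  if (is.null(normal)) {
    if (is.null(angle))
      stop("supply either `normal` or `angle`")
    a <- angle * pi / 180
    normal <- c(cos(a), sin(a))
  }
  nrm <- sqrt(sum(normal^2))
  if (!is.finite(nrm) || nrm == 0) stop("normal must be non-zero")
  new("VesselGeometry", center = as.numeric(center),
      normal = as.numeric(normal) / nrm, r = as.numeric(r),
      scale = as.numeric(scale))
}

#' Contractility summary for one trace and analysis window
#'
#' The package's phasic-contractility outcome measures for one trace over one
#' analysis window: contraction frequency (peaks per minute), percent
#' amplitude (mean per-cycle peak-minus-trough expressed as percent of the
#' instantaneous mean), their product the pumping score, and the window mean
#' level (the basis of tone comparisons).
#'
#' A quiescent trace (no detected peaks) has frequency 0, undefined (NA)
#' percent amplitude, and pumping score 0.
#'
#' @slot frequency contractions per minute.
#' @slot pctAmplitude mean per-cycle amplitude, percent of instantaneous mean
#'   (NA when no complete interior cycle exists).
#' @slot pumpingScore frequency times percent amplitude.
#' @slot meanLevel mean of the raw trace over the window (trace units).
#' @slot nCycles number of complete interior contraction cycles measured.
#' @slot window analysis window (start, end) in seconds.
#' @slot cycles per-cycle measurement table (see [measureCycles()]).
#' @export
setClass("ContractilitySummary",
  representation(frequency = "numeric", pctAmplitude = "numeric",
                 pumpingScore = "numeric", meanLevel = "numeric",
                 nCycles = "integer", window = "numeric",
                 cycles = "data.frame")
)

setValidity("ContractilitySummary", function(object) {
  msg <- character(0)
  if (length(object@frequency) != 1 || (is.finite(object@frequency) &&
      object@frequency < 0))
    msg <- c(msg, "frequency must be a single non-negative number")
  if (object@nCycles < 0)
    msg <- c(msg, "nCycles must be non-negative")
  if (length(object@window) != 2 || diff(object@window) <= 0)
    msg <- c(msg, "window must be (start, end) with end > start")
  f <- object@frequency; a <- object@pctAmplitude; s <- object@pumpingScore
  if (is.finite(f) && is.finite(a) && is.finite(s) &&
      abs(s - f * a) > 1e-8 * max(1, abs(s)))
    msg <- c(msg, "pumpingScore must equal frequency * pctAmplitude")
  if (length(msg)) msg else TRUE
})

#' Baseline-normalized treatment effect
#'
#' Post-treatment contractility expressed as percent of the pre-treatment
#' (baseline) value for each outcome measure, following the convention of
#' normalizing baseline measurements to 100%. Tone is the ratio of window
#' mean levels (mean fluorescence or diameter), with values below 100%
#' indicating constriction.
#'
#' @slot baseline [ContractilitySummary-class] for the baseline window.
#' @slot post [ContractilitySummary-class] for the post-treatment window.
#' @slot percents named numeric: \code{frequency}, \code{amplitude},
#'   \code{pumping}, \code{tone}, each percent of baseline (NA where the
#'   baseline value is zero or undefined).
#' @export
setClass("TreatmentEffect",
  representation(baseline = "ContractilitySummary",
                 post = "ContractilitySummary",
                 percents = "numeric")
)

setValidity("TreatmentEffect", function(object) {
  need <- c("frequency", "amplitude", "pumping", "tone")
  if (!all(need %in% names(object@percents)))
    return("percents must contain frequency, amplitude, pumping, tone")
  TRUE
})
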