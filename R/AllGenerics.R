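# Generics and accessors for the package classes.

#' @rdname Trace-class
#' @param x,object a \code{Trace}.
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))
#' @rdname Trace-class
#' @export
setMethod("traceValues", "Trace", function(x) x@values)

#' @rdname Trace-class
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname Trace-class
#' @export
setMethod("sampleRate", "Trace", function(x) x@sampleRate)

#' @rdname Trace-class
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))
#' @rdname Trace-class
#' @export
setMethod("startTime", "Trace", function(x) x@t0)

#' @rdname Trace-class
#' @details \code{traceTimes()} returns the sample times in seconds.
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))
#' @rdname Trace-class
#' @export
setMethod("traceTimes", "Trace", function(x)
  x@t0 + (seq_along(x@values) - 1) / x@sampleRate)

#' @rdname Trace-class
#' @export
setMethod("length", "Trace", function(x) length(x@values))

#' @rdname Trace-class
#' @export
setMethod("show", "Trace", function(object) {
  v <- object@values
  cat(sprintf("Trace: %d samples at %g /s, t = [%g, %g] s\n",
              length(v), object@sampleRate, object@t0,
              object@t0 + (length(v) - 1) / object@sampleRate))
  cat(sprintf("  values: mean %.4g, range [%.4g, %.4g]\n",
              mean(v), min(v), max(v)))
})

#' Extract a time window from a Trace
#'
#' Returns the samples with time in \code{[from, to)} as a new \code{Trace}
#' (times are relative to the same clock as \code{startTime(x)}).
#'
#' @param x a [Trace-class].
#' @param from,to window limits in seconds.
#' @return A [Trace-class].
#' @export
windowTrace <- function(x, from, to) {
  stopifnot(is(x, "Trace"))
  if (!is.finite(from) || !is.finite(to) || to <= from)
    stop("invalid window: need to > from")
  t <- traceTimes(x)
  keep <- t >= from - 1e-9 & t < to - 1e-9
  if (sum(keep) < 10)
    stop("window contains fewer than 10 samples")
  Trace(x@values[keep], x@sampleRate, t0 = t[which(keep)[1]])
}

#' @rdname PeakTroughSet-class
#' @param x,object a \code{PeakTroughSet}.
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))
#' @rdname PeakTroughSet-class
#' @export
setMethod("peaks", "PeakTroughSet", function(x) x@peaks)

#' @rdname PeakTroughSet-class
#' @export
setGeneric("troughs", function(x) standardGeneric("troughs"))
#' @rdname PeakTroughSet-class
#' @export
setMethod("troughs", "PeakTroughSet", function(x) x@troughs)

#' @rdname PeakTroughSet-class
#' @export
setMethod("show", "PeakTroughSet", function(object) {
  cat(sprintf("PeakTroughSet: %d peaks, %d troughs (n = %d samples)\n",
              length(object@peaks), length(object@troughs), object@n))
  cat(sprintf("  selected scales: lambda = %d (peaks), %d (troughs)\n",
              object@scalePeaks@lambda, object@scaleTroughs@lambda))
})

#' @rdname ScaleSelection-class
#' @param object a \code{ScaleSelection}.
#' @export
setMethod("show", "ScaleSelection", function(object) {
  cat(sprintf("ScaleSelection: lambda = %d of L = %d scales (gamma = %.3g)\n",
              object@lambda, object@L, object@gamma[object@lambda]))
})

#' @rdname ContractilitySummary-class
#' @param x,object a \code{ContractilitySummary}.
#' @export
setGeneric("frequency", function(x, ...) standardGeneric("frequency"))
#' @rdname ContractilitySummary-class
#' @export
setMethod("frequency", "ContractilitySummary", function(x, ...) x@frequency)

#' @rdname ContractilitySummary-class
#' @export
setGeneric("pctAmplitude", function(x) standardGeneric("pctAmplitude"))
#' @rdname ContractilitySummary-class
#' @export
setMethod("pctAmplitude", "ContractilitySummary", function(x) x@pctAmplitude)

#' @rdname ContractilitySummary-class
#' @export
setGeneric("pumpingScore", function(x, ...) standardGeneric("pumpingScore"))

#' @rdname ContractilitySummary-class
#' @export
setMethod("pumpingScore", "ContractilitySummary", function(x, ...) x@pumpingScore)

#' @rdname ContractilitySummary-class
#' @export
setGeneric("meanLevel", function(x) standardGeneric("meanLevel"))
#' @rdname ContractilitySummary-class
#' @export
setMethod("meanLevel", "ContractilitySummary", function(x) x@meanLevel)

#' @rdname ContractilitySummary-class
#' @export
setGeneric("nCycles", function(x) standardGeneric("nCycles"))
#' @rdname ContractilitySummary-class
#' @export
setMethod("nCycles", "ContractilitySummary", function(x) x@nCycles)

#' @rdname ContractilitySummary-class
#' @details \code{cycleTable()} returns the per-cycle measurement table.
#' @export
setGeneric("cycleTable", function(x) standardGeneric("cycleTable"))
#' @rdname ContractilitySummary-class
#' @export
setMethod("cycleTable", "ContractilitySummary", function(x) x@cycles)

#' @rdname ContractilitySummary-class
#' @export
setMethod("show", "ContractilitySummary", function(object) {
  cat(sprintf("ContractilitySummary over [%g, %g] s\n",
              object@window[1], object@window[2]))
  cat(sprintf("  frequency     %8.3f /min\n", object@frequency))
  cat(sprintf("  %% amplitude   %8.3f %% of instantaneous mean (n = %d cycles)\n",
              object@pctAmplitude, object@nCycles))
  cat(sprintf("  pumping score %8.3f\n", object@pumpingScore))
  cat(sprintf("  mean level    %8.3f (trace units)\n", object@meanLevel))
})

#' @rdname TreatmentEffect-class
#' @param x,object a \code{TreatmentEffect}.
#' @details \code{effectPercents()} returns the named percent-of-baseline
#'   vector (frequency, amplitude, pumping, tone).
#' @export
setGeneric("effectPercents", function(x) standardGeneric("effectPercents"))
#' @rdname TreatmentEffect-class
#' @export
setMethod("effectPercents", "TreatmentEffect", function(x) x@percents)

#' @rdname TreatmentEffect-class
#' @export
setMethod("show", "TreatmentEffect", function(object) {
  p <- object@percents
  cat("TreatmentEffect (percent of baseline):\n")
  cat(sprintf("  frequency %7.2f %%   amplitude %7.2f %%\n",
              p[["frequency"]], p[["amplitude"]]))
  cat(sprintf("  pumping   %7.2f %%   tone      %7.2f %%\n",
              p[["pumping"]], p[["tone"]]))
})

#' @rdname VesselGeometry-class
#' @param object a \code{VesselGeometry}.
#' @export
setMethod("show", "VesselGeometry", function(object) {
  cat(sprintf(
    "VesselGeometry: center (%.1f, %.1f) px, normal (%.3f, %.3f), r = %g px, %g um/px\n",
    object@center[1], object@center[2], object@normal[1], object@normal[2],
    object@r, object@scale))
})
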