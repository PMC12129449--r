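#' @include AllClasses.R
NULL

#' Accessors for SignalTrace objects
#'
#' @param x a [SignalTrace-class] (or derived) object.
#' @return `samples()` the numeric sample vector; `samplingRate()` the rate in
#'   samples/s; `traceUnits()` and `channelLabel()` character labels;
#'   `startTime()` the time of the first sample; `traceTimes()` the vector of
#'   sample times in seconds; `traceDuration()` the spanned duration in
#'   seconds; `nSamples()` the number of samples.
#' @name trace-accessors
#' @aliases samples samplingRate traceUnits channelLabel startTime traceTimes
#'   traceDuration nSamples
NULL

#' @rdname trace-accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname trace-accessors
#' @export
setMethod("samples", "SignalTrace", function(x) x@samples)

#' @rdname trace-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname trace-accessors
#' @export
setMethod("samplingRate", "SignalTrace", function(x) x@samplingRate)

#' @rdname trace-accessors
#' @export
setGeneric("traceUnits", function(x) standardGeneric("traceUnits"))
#' @rdname trace-accessors
#' @export
setMethod("traceUnits", "SignalTrace", function(x) x@units)

#' @rdname trace-accessors
#' @export
setGeneric("channelLabel", function(x) standardGeneric("channelLabel"))
#' @rdname trace-accessors
#' @export
setMethod("channelLabel", "SignalTrace", function(x) x@channel)

#' @rdname trace-accessors
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))
#' @rdname trace-accessors
#' @export
setMethod("startTime", "SignalTrace", function(x) x@startTime)

#' @rdname trace-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname trace-accessors
#' @export
setMethod("nSamples", "SignalTrace", function(x) length(x@samples))

#' @rdname trace-accessors
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))
#' @rdname trace-accessors
#' @export
setMethod("traceTimes", "SignalTrace", function(x) {
  x@startTime + (seq_along(x@samples) - 1L) / x@samplingRate
})

#' @rdname trace-accessors
#' @export
setGeneric("traceDuration", function(x) standardGeneric("traceDuration"))
#' @rdname trace-accessors
#' @export
setMethod("traceDuration", "SignalTrace", function(x) {
  length(x@samples) / x@samplingRate
})

#' @describeIn Envelope-class smoothing provenance (band, window widths).
#' @param x an `Envelope`.
#' @export
setGeneric("smoothingParams", function(x) standardGeneric("smoothingParams"))
#' @rdname Envelope-class
#' @export
setMethod("smoothingParams", "Envelope", function(x) x@smoothing)

#' Accessors for GroundTruth tables
#'
#' @param x a [GroundTruth-class] object.
#' @return The requested event table (data.frame).
#' @name truth-accessors
NULL

#' @rdname truth-accessors
#' @export
setGeneric("truthBursts", function(x) standardGeneric("truthBursts"))
#' @rdname truth-accessors
#' @export
setMethod("truthBursts", "GroundTruth", function(x) x@bursts)

#' @rdname truth-accessors
#' @export
setGeneric("truthBeats", function(x) standardGeneric("truthBeats"))
#' @rdname truth-accessors
#' @export
setMethod("truthBeats", "GroundTruth", function(x) x@beats)

#' @rdname truth-accessors
#' @export
setGeneric("truthBreaths", function(x) standardGeneric("truthBreaths"))
#' @rdname truth-accessors
#' @export
setMethod("truthBreaths", "GroundTruth", function(x) x@breaths)

#' Accessors for TestResult objects
#'
#' @param x a [TestResult-class] object.
#' @return `pValue()` the (uncorrected) p-value; `statistic()` the test
#'   statistic; `effectsTable()` the per-effect table for factorial ANOVAs;
#'   `postHoc()` the pairwise post hoc table.
#' @name testresult-accessors
NULL

#' @rdname testresult-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname testresult-accessors
#' @export
setMethod("pValue", "TestResult", function(x) x@pValue)

#' @rdname testresult-accessors
#' @export
setGeneric("statistic", function(x) standardGeneric("statistic"))
#' @rdname testresult-accessors
#' @export
setMethod("statistic", "TestResult", function(x) x@statistic)

#' @rdname testresult-accessors
#' @export
setGeneric("effectsTable", function(x) standardGeneric("effectsTable"))
#' @rdname testresult-accessors
#' @export
setMethod("effectsTable", "TestResult", function(x) x@effects)

#' @rdname testresult-accessors
#' @export
setGeneric("postHoc", function(x) standardGeneric("postHoc"))
#' @rdname testresult-accessors
#' @export
setMethod("postHoc", "TestResult", function(x) x@postHoc)

setMethod("show", "SignalTrace", function(object) {
  cat(sprintf("%s: %d samples @ %g S/s (%.3f s)%s%s\n",
              class(object), length(object@samples), object@samplingRate,
              traceDuration(object),
              if (nzchar(object@channel)) paste0(", channel ", object@channel)
              else "",
              paste0(", units ", object@units)))
})

setMethod("show", "Envelope", function(object) {
  callNextMethod()
  s <- object@smoothing
  cat(sprintf("  smoothing: median %g ms, mean %g ms\n",
              s$median_ms, s$mean_ms))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %.1f s @ %g S/s, %g bursts/min x %g ms, phasic %g, tonic %g\n",
    object@durationS, object@samplingRateHz, object@burstRatePerMin,
    object@burstDurationMs, object@phasicAmplitude, object@tonicLevel))
  cat(sprintf("  carrier %g-%g Hz, noise floor %g, seed %d\n",
              object@carrierBandHz[1], object@carrierBandHz[2],
              object@noiseFloor, object@seed))
  if (!is.null(object@intervention)) {
    iv <- object@intervention
    cat(sprintf(
      "  intervention at %g s: amp x%g, tonic x%g, rate x%g, ramp %g s\n",
      iv@onsetS, iv@amplitudeGain, iv@tonicGain, iv@rateFactor, iv@rampS))
  }
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d bursts, %d beats, %d breaths\n",
              nrow(object@bursts), nrow(object@beats),
              nrow(object@breaths)))
})

setMethod("show", "PlethCalibration", function(object) {
  cat(sprintf(
    "PlethCalibration: VK %g ml -> PK %g; TR %.2f K, TC %.2f K, PB %g mmHg, RH %.2f, mass %g kg\n",
    object@vkMl, object@pkDefl, object@trK, object@tcK, object@pbMmhg,
    object@rhFrac, object@bodyMassKg))
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("TestResult: %s\n", object@testName))
  if (nrow(object@effects)) {
    print(object@effects, row.names = FALSE)
  } else if (!is.na(object@statistic)) {
    dfs <- paste(signif(object@df, 6), collapse = ", ")
    cat(sprintf("  statistic = %.6g, df = %s, p = %.5g\n",
                object@statistic, dfs, object@pValue))
  }
  if (!is.na(object@pGG)) {
    cat(sprintf("  Greenhouse-Geisser p = %.5g\n", object@pGG))
  }
  if (nrow(object@postHoc)) {
    cat(sprintf("  post hoc (%s): %d comparisons\n", object@correction,
                nrow(object@postHoc)))
  }
})
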