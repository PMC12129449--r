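#' @import methods
NULL

#' Uniformly sampled physiological signal
#'
#' `SignalTrace` holds one uniformly sampled channel (diaphragm EMG, phrenic
#' neurogram, arterial pressure or plethysmograph chamber pressure) together
#' with its sampling rate, units and start time. All times in the package are
#' seconds from recording start.
#'
#' @slot samples numeric vector of samples.
#' @slot samplingRate sampling rate in samples per second.
#' @slot units character unit label (e.g. "mV", "mmHg", "a.u.").
#' @slot channel character channel label (e.g. "dia_L", "ABP").
#' @slot startTime start time of the first sample, seconds.
#'
#' @examples
#' tr <- SignalTrace(sin(seq(0, 1, by = 1e-3)), samplingRate = 1000)
#' samplingRate(tr)
#' traceDuration(tr)
#' @export
setClass("SignalTrace",
  representation(
    samples = "numeric",
    samplingRate = "numeric",
    units = "character",
    channel = "character",
    startTime = "numeric"
  ),
  prototype(units = "a.u.", channel = "", startTime = 0)
)

setValidity("SignalTrace", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0) {
    msg <- c(msg, "samplingRate must be a single positive finite number")
  }
  if (length(object@samples) < 1L) {
    msg <- c(msg, "samples must contain at least one value")
  }
  if (anyNA(object@samples) || any(!is.finite(object@samples))) {
    msg <- c(msg, "samples must be finite")
  }
  if (length(object@startTime) != 1L || !is.finite(object@startTime)) {
    msg <- c(msg, "startTime must be a single finite number")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname SignalTrace-class
#' @param samples numeric vector of samples.
#' @param samplingRate sampling rate, samples/s.
#' @param units unit label.
#' @param channel channel label.
#' @param startTime time of the first sample, seconds.
#' @return A [SignalTrace-class] object.
#' @export
SignalTrace <- function(samples, samplingRate, units = "a.u.", channel = "",
                        startTime = 0) {
  new("SignalTrace", samples = as.numeric(samples),
      samplingRate = as.numeric(samplingRate), units = units,
      channel = channel, startTime = as.numeric(startTime))
}

#' Rectified-integrated activity envelope
#'
#' An `Envelope` is a [SignalTrace-class] produced by [signalEnvelope()]:
#' the absolute value of a (filtered) signal smoothed by a centered moving
#' median and then a centered moving average. Values are nonnegative and the
#' trace keeps the length and rate of its source. The `smoothing` slot records
#' provenance: the band of the preceding filter (if any) and both window
#' widths in ms.
#'
#' @slot smoothing list with elements `band_hz`, `median_ms`, `mean_ms`.
#' @export
setClass("Envelope",
  contains = "SignalTrace",
  representation(smoothing = "list"),
  prototype(smoothing = list(band_hz = NULL, median_ms = NA_real_,
                             mean_ms = NA_real_))
)

setValidity("Envelope", function(object) {
  if (any(object@samples < 0)) {
    "envelope samples must be nonnegative"
  } else TRUE
})

#' Ligand-intervention effect specification
#'
#' Describes a sustained intervention effect (e.g. DREADD activation by an
#' agonist such as J60) applied from `onsetS` to the end of the trace:
#' multiplicative gains on phasic burst amplitude, tonic level and burst rate,
#' reached linearly over `rampS` seconds and held thereafter.
#'
#' @slot onsetS effect onset, seconds.
#' @slot amplitudeGain multiplier on phasic burst amplitude (>= 0).
#' @slot tonicGain multiplier on tonic level (>= 0).
#' @slot rateFactor multiplier on burst rate (>= 0).
#' @slot rampS seconds to reach the full effect (>= 0).
#' @export
setClass("InterventionSpec",
  representation(onsetS = "numeric", amplitudeGain = "numeric",
                 tonicGain = "numeric", rateFactor = "numeric",
                 rampS = "numeric")
)

setValidity("InterventionSpec", function(object) {
  msg <- character()
  for (nm in c("onsetS", "amplitudeGain", "tonicGain", "rateFactor",
               "rampS")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v)) {
      msg <- c(msg, sprintf("%s must be a single finite number", nm))
    }
  }
  if (!length(msg)) {
    if (object@amplitudeGain < 0) msg <- c(msg, "amplitudeGain must be >= 0")
    if (object@tonicGain < 0) msg <- c(msg, "tonicGain must be >= 0")
    if (object@rateFactor < 0) msg <- c(msg, "rateFactor must be >= 0")
    if (object@rampS < 0) msg <- c(msg, "rampS must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname InterventionSpec-class
#' @param onsetS,amplitudeGain,tonicGain,rateFactor,rampS see slots.
#' @return An [InterventionSpec-class] object.
#' @export
interventionSpec <- function(onsetS, amplitudeGain = 1, tonicGain = 1,
                             rateFactor = 1, rampS = 0) {
  new("InterventionSpec", onsetS = as.numeric(onsetS),
      amplitudeGain = as.numeric(amplitudeGain),
      tonicGain = as.numeric(tonicGain),
      rateFactor = as.numeric(rateFactor), rampS = as.numeric(rampS))
}

setClassUnion("InterventionSpecOrNULL", c("InterventionSpec", "NULL"))

#' Synthetic EMG/neurogram simulation configuration
#'
#' Configuration of the inspiratory burst-train simulator ([simulateEmg()]).
#' The generated raw-style signal is a band-limited Gaussian carrier
#' amplitude-modulated by `tonicLevel` plus a per-burst raised-cosine
#' envelope of height `phasicAmplitude`, with additive broadband noise of
#' standard deviation `noiseFloor`. Defaults emulate an anesthetized-mouse
#' diaphragm EMG rig: 10 kS/s digitization, 100--1000 Hz interference-pattern
#' carrier, ~90 inspiratory bursts/min of 180 ms with a tonic floor at 15%
#' of the phasic amplitude and a broadband noise floor at 5%.
#'
#' @slot durationS trace duration, seconds.
#' @slot samplingRateHz sampling rate, samples/s; must exceed twice the upper
#'   carrier band edge.
#' @slot burstRatePerMin mean inspiratory burst rate, events/min.
#' @slot burstDurationMs burst duration, ms.
#' @slot phasicAmplitude envelope peak above tonic, signal units.
#' @slot tonicLevel tonic (between-burst) envelope level, signal units.
#' @slot carrierBandHz length-2 numeric, (low, high) Hz of the carrier band.
#' @slot noiseFloor additive broadband noise SD, signal units.
#' @slot intervention optional [InterventionSpec-class].
#' @slot seed integer RNG seed; identical configs give bit-identical output.
#' @export
setClass("SimConfig",
  representation(
    durationS = "numeric", samplingRateHz = "numeric",
    burstRatePerMin = "numeric", burstDurationMs = "numeric",
    phasicAmplitude = "numeric", tonicLevel = "numeric",
    carrierBandHz = "numeric", noiseFloor = "numeric",
    intervention = "InterventionSpecOrNULL", seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  one <- function(nm) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v)) {
      msg <<- c(msg, sprintf("%s must be a single finite number", nm))
      FALSE
    } else TRUE
  }
  for (nm in c("durationS", "samplingRateHz", "burstRatePerMin",
               "burstDurationMs", "phasicAmplitude", "tonicLevel",
               "noiseFloor")) one(nm)
  if (!length(msg)) {
    if (object@durationS <= 0) msg <- c(msg, "durationS must be > 0")
    if (object@burstRatePerMin <= 0)
      msg <- c(msg, "burstRatePerMin must be > 0")
    if (object@burstDurationMs <= 0)
      msg <- c(msg, "burstDurationMs must be > 0")
    if (object@phasicAmplitude < 0)
      msg <- c(msg, "phasicAmplitude must be >= 0")
    if (object@tonicLevel < 0) msg <- c(msg, "tonicLevel must be >= 0")
    if (object@noiseFloor < 0) msg <- c(msg, "noiseFloor must be >= 0")
    if (length(object@carrierBandHz) != 2L ||
        any(!is.finite(object@carrierBandHz)) ||
        object@carrierBandHz[1] <= 0 ||
        object@carrierBandHz[1] >= object@carrierBandHz[2]) {
      msg <- c(msg, "carrierBandHz must be (low, high) with 0 < low < high")
    } else if (object@samplingRateHz <= 2 * object@carrierBandHz[2]) {
      msg <- c(msg,
        "samplingRateHz must exceed twice the upper carrierBandHz edge")
    }
    if (length(object@seed) != 1L || is.na(object@seed)) {
      msg <- c(msg, "seed must be a single integer")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param durationS,samplingRateHz,burstRatePerMin,burstDurationMs see slots.
#' @param phasicAmplitude,tonicLevel,carrierBandHz,noiseFloor see slots.
#' @param intervention optional [InterventionSpec-class] (or `NULL`).
#' @param seed integer RNG seed.
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(durationS = 10, seed = 1)
#' sim <- simulateEmg(cfg)
#' nrow(truthBursts(sim$truth))
#' @export
simConfig <- function(durationS = 60, samplingRateHz = 10000,
                      burstRatePerMin = 90, burstDurationMs = 180,
                      phasicAmplitude = 1, tonicLevel = 0.15,
                      carrierBandHz = c(100, 1000), noiseFloor = 0.05,
                      intervention = NULL, seed = 1L) {
  new("SimConfig", durationS = as.numeric(durationS),
      samplingRateHz = as.numeric(samplingRateHz),
      burstRatePerMin = as.numeric(burstRatePerMin),
      burstDurationMs = as.numeric(burstDurationMs),
      phasicAmplitude = as.numeric(phasicAmplitude),
      tonicLevel = as.numeric(tonicLevel),
      carrierBandHz = as.numeric(carrierBandHz),
      noiseFloor = as.numeric(noiseFloor),
      intervention = intervention, seed = as.integer(seed))
}

#' Exact ground truth of a simulated trace
#'
#' Event-level truth stored by the simulators: burst windows with true peak
#' envelope, tonic level and AUC ([simulateEmg()]); beat times with true
#' systolic/diastolic pressure ([simulateArterialPressure()]); breath windows
#' with true deflection and tidal volume ([simulatePleth()]). Tables not
#' produced by a given simulator are empty.
#'
#' @slot bursts data.frame: onset_s, offset_s, peak_time_s, peak_env, tonic,
#'   amplitude, auc.
#' @slot beats data.frame: start_s, end_s, sp, dp.
#' @slot breaths data.frame: onset_s, offset_s, deflection, vt_ml.
#' @export
setClass("GroundTruth",
  representation(bursts = "data.frame", beats = "data.frame",
                 breaths = "data.frame"),
  prototype(bursts = data.frame(), beats = data.frame(),
            breaths = data.frame())
)

setValidity("GroundTruth", function(object) {
  b <- object@bursts
  if (nrow(b)) {
    if (is.unsorted(b$onset_s, strictly = TRUE)) {
      return("burst onsets must be strictly increasing")
    }
    if (any(b$offset_s <= b$onset_s)) {
      return("burst offsets must exceed matching onsets")
    }
  }
  TRUE
})

#' Whole-body plethysmograph calibration
#'
#' Chamber and animal constants feeding the Drorbaugh-Fenn tidal volume
#' equation ([drorbaughFennVt()]): a known calibration volume `vkMl` injected
#' into the chamber producing pressure deflection `pkDefl`, body (rectal) and
#' chamber temperatures in Kelvin, barometric pressure in mmHg, chamber
#' relative humidity as a fraction, and the animal's body mass used for
#' weight normalization.
#'
#' @slot vkMl calibration volume, ml.
#' @slot pkDefl pressure deflection produced by `vkMl`, pressure units.
#' @slot trK body (rectal) temperature, Kelvin.
#' @slot tcK chamber temperature, Kelvin.
#' @slot pbMmhg barometric pressure, mmHg.
#' @slot rhFrac chamber relative humidity, in [0, 1].
#' @slot bodyMassKg body mass, kg.
#' @export
setClass("PlethCalibration",
  representation(vkMl = "numeric", pkDefl = "numeric", trK = "numeric",
                 tcK = "numeric", pbMmhg = "numeric", rhFrac = "numeric",
                 bodyMassKg = "numeric")
)

setValidity("PlethCalibration", function(object) {
  msg <- character()
  for (nm in c("vkMl", "pkDefl", "trK", "tcK", "pbMmhg", "bodyMassKg")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v) || v <= 0) {
      msg <- c(msg, sprintf("%s must be a single positive number", nm))
    }
  }
  if (length(object@rhFrac) != 1L || !is.finite(object@rhFrac) ||
      object@rhFrac < 0 || object@rhFrac > 1) {
    msg <- c(msg, "rhFrac must lie in [0, 1]")
  }
  if (!length(msg)) {
    den <- .dfDenominator(object)
    if (!is.finite(den) || den <= 0) {
      msg <- c(msg, paste0(
        "degenerate plethysmograph physics: the Drorbaugh-Fenn denominator ",
        "TR*(PB - PC) - TC*(PB - PR) is not positive for trK=", object@trK,
        ", tcK=", object@tcK, ", pbMmhg=", object@pbMmhg,
        ", rhFrac=", object@rhFrac))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname PlethCalibration-class
#' @param vkMl,pkDefl,trK,tcK,pbMmhg,rhFrac,bodyMassKg see slots.
#' @return A [PlethCalibration-class] object.
#' @examples
#' cal <- plethCalibration()
#' drorbaughFennVt(cal@pkDefl, cal)  # one calibration deflection
#' @export
plethCalibration <- function(vkMl = 1, pkDefl = 1, trK = 310.15,
                             tcK = 297.15, pbMmhg = 760, rhFrac = 0.5,
                             bodyMassKg = 0.35) {
  new("PlethCalibration", vkMl = as.numeric(vkMl),
      pkDefl = as.numeric(pkDefl), trK = as.numeric(trK),
      tcK = as.numeric(tcK), pbMmhg = as.numeric(pbMmhg),
      rhFrac = as.numeric(rhFrac), bodyMassKg = as.numeric(bodyMassKg))
}

#' Result of a statistical test
#'
#' Container returned by the statistical battery. Omnibus ANOVAs populate
#' `effects` (one row per effect); simple tests populate `statistic`, `df`
#' and `pValue`. `postHoc` holds Tukey pairwise comparisons when computed.
#'
#' @slot testName character label of the test.
#' @slot statistic test statistic (NA when `effects` carries the result).
#' @slot df degrees of freedom (length 1 or 2).
#' @slot pValue p-value in [0, 1].
#' @slot pGG Greenhouse-Geisser corrected p (RM-ANOVA only, else NA).
#' @slot effects data.frame of per-effect F tests (two-way RM-ANOVA).
#' @slot postHoc data.frame of pairwise comparisons with adjusted p.
#' @slot correction character label of any p adjustment.
#' @slot details list of test-specific context (means, error MS, ...).
#' @export
setClass("TestResult",
  representation(testName = "character", statistic = "numeric",
                 df = "numeric", pValue = "numeric", pGG = "numeric",
                 effects = "data.frame", postHoc = "data.frame",
                 correction = "character", details = "list"),
  prototype(statistic = NA_real_, df = NA_real_, pValue = NA_real_,
            pGG = NA_real_, effects = data.frame(), postHoc = data.frame(),
            correction = "none", details = list())
)

setValidity("TestResult", function(object) {
  p <- object@pValue
  if (length(p) == 1L && !is.na(p) && (p < 0 || p > 1)) {
    return("pValue must lie in [0, 1]")
  }
  TRUE
})

.TestResult <- function(testName, statistic = NA_real_, df = NA_real_,
                        pValue = NA_real_, pGG = NA_real_,
                        effects = data.frame(), postHoc = data.frame(),
                        correction = "none", details = list()) {
  new("TestResult", testName = testName, statistic = as.numeric(statistic),
      df = as.numeric(df), pValue = as.numeric(pValue),
      pGG = as.numeric(pGG), effects = effects, postHoc = postHoc,
      correction = correction, details = details)
}
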