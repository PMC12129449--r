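#' @include detect.R
NULL

# Magnus-Tetens saturation vapor pressure, mmHg, temp in Kelvin.
.satVaporMmhg <- function(tempK) {
  tc <- tempK - 273.15
  6.1078 * 10^(7.5 * tc / (tc + 237.3)) * 0.750062
}

.dfNumerator <- function(calib) {
  pc <- calib@rhFrac * .satVaporMmhg(calib@tcK)
  calib@trK * (calib@pbMmhg - pc)
}

.dfDenominator <- function(calib) {
  pr <- .satVaporMmhg(calib@trK)
  .dfNumerator(calib) - calib@tcK * (calib@pbMmhg - pr)
}

# Drorbaugh-Fenn correction factor (dimensionless, > 1 at physiological
# conditions since the denominator subtracts the body-temperature term).
.dfFactor <- function(calib) .dfNumerator(calib) / .dfDenominator(calib)

#' Water vapor pressure
#'
#' Saturation vapor pressure by the Magnus-Tetens approximation,
#' `6.1078 * 10^(7.5 T / (T + 237.3))` hPa with `T` in degrees Celsius,
#' converted to mmHg and scaled by relative humidity. Accurate to about
#' 0.1 mmHg between 0 and 50 degrees C.
#'
#' @param tempK temperature in Kelvin (230 < tempK < 380).
#' @param rhFrac relative humidity fraction in [0, 1] (1 = saturated).
#' @return vapor pressure in mmHg.
#' @examples
#' waterVaporPressure(298.15)         # ~23.8 mmHg at 25 C, saturated
#' waterVaporPressure(310.15, 0.5)    # half-saturated at body temperature
#' @export
waterVaporPressure <- function(tempK, rhFrac = 1) {
  if (any(!is.finite(tempK)) || any(tempK <= 230) || any(tempK >= 380)) {
    stop("tempK out of supported range (230, 380) K")
  }
  if (any(!is.finite(rhFrac)) || any(rhFrac < 0) || any(rhFrac > 1)) {
    stop("rhFrac must lie in [0, 1]")
  }
  rhFrac * .satVaporMmhg(tempK)
}

#' Drorbaugh-Fenn tidal volume
#'
#' Converts a plethysmograph pressure deflection to tidal volume:
#' \deqn{V_T = P_T \frac{V_K}{P_K}
#'   \frac{T_R (P_B - P_C)}{T_R (P_B - P_C) - T_C (P_B - P_R)}}
#' where \eqn{V_K} is the calibration volume producing deflection
#' \eqn{P_K}, \eqn{T_R} and \eqn{T_C} are body and chamber temperature
#' (Kelvin), \eqn{P_B} the barometric pressure, \eqn{P_C} the chamber
#' water vapor pressure (humidity times saturation at \eqn{T_C}) and
#' \eqn{P_R} the saturation vapor pressure at body temperature. The
#' result is linear in the deflection and in \eqn{V_K}.
#'
#' @param deflectionPt peak inspiratory pressure deflection(s), same units
#'   as `pkDefl` of the calibration; nonnegative.
#' @param calib a [PlethCalibration-class].
#' @return tidal volume(s) in ml.
#' @examples
#' cal <- plethCalibration(trK = 310.15, tcK = 298.15, pbMmhg = 760,
#'                         rhFrac = 0.5)
#' drorbaughFennVt(1, cal)  # correction factor for PT = PK, VK = 1 ml
#' @export
drorbaughFennVt <- function(deflectionPt, calib) {
  stopifnot(is(calib, "PlethCalibration"))
  validObject(calib)
  if (any(!is.finite(deflectionPt)) || any(deflectionPt < 0)) {
    stop("deflectionPt must be finite and >= 0")
  }
  den <- .dfDenominator(calib)
  if (den <= 0) {
    stop("degenerate plethysmograph physics: Drorbaugh-Fenn denominator <= 0")
  }
  deflectionPt * (calib@vkMl / calib@pkDefl) * .dfFactor(calib)
}

#' Per-burst envelope metrics
#'
#' For each detected burst computes the quantities reported for diaphragm
#' EMG and phrenic neurograms: peak amplitude (envelope maximum within the
#' burst), tonic activity (envelope minimum in a pre-onset window),
#' peak-to-peak amplitude (peak minus tonic) and AUC (trapezoidal integral
#' of the raw envelope over the burst, no baseline subtraction; a
#' tonic-subtracted variant is returned as `auc_net`).
#'
#' The tonic window is a short (default 75 ms) interval immediately
#' before the onset: the minimum over a long window of a fluctuating
#' envelope is biased low, so a window on the order of the smoothing
#' width estimates the between-burst floor with the least bias. Passing
#' `tonicWindowS = NULL` uses 50% of the preceding inter-burst gap
#' instead. The first burst, which has no preceding gap, uses the
#' trailing gap and is flagged in `tonic_source`.
#'
#' @param env an [Envelope-class].
#' @param bursts data.frame of events from [detectBursts()] (or ground
#'   truth), with `onset_s` and `offset_s`.
#' @param tonicWindowS fixed tonic window length in seconds (default
#'   0.075), or `NULL` for half the preceding inter-burst gap.
#' @return data.frame with one row per burst: `onset_s`, `offset_s`,
#'   `peak_time_s`, `peak_amp`, `tonic`, `pk_pk`, `auc`, `auc_net`,
#'   `tonic_source`.
#' @export
burstMetrics <- function(env, bursts, tonicWindowS = 0.075) {
  stopifnot(is(env, "Envelope"))
  nb <- nrow(bursts)
  if (!nb) {
    return(data.frame(onset_s = numeric(), offset_s = numeric(),
                      peak_time_s = numeric(), peak_amp = numeric(),
                      tonic = numeric(), pk_pk = numeric(),
                      auc = numeric(), auc_net = numeric(),
                      tonic_source = character()))
  }
  v <- samples(env)
  rate <- samplingRate(env)
  t0 <- startTime(env)
  n <- length(v)
  idxOf <- function(tt) pmin(pmax(round((tt - t0) * rate) + 1L, 1L), n)
  dt <- 1 / rate

  peak <- numeric(nb); peakT <- numeric(nb); auc <- numeric(nb)
  for (i in seq_len(nb)) {
    a <- idxOf(bursts$onset_s[i]); b <- idxOf(bursts$offset_s[i])
    if (b <= a) stop("burst ", i, " lies outside the envelope support")
    seg <- v[a:b]
    j <- which.max(seg)
    peak[i] <- seg[j]
    peakT[i] <- t0 + (a + j - 2L) / rate
    auc[i] <- (sum(seg) - (seg[1L] + seg[length(seg)]) / 2) * dt
  }

  tonic <- numeric(nb)
  src <- character(nb)
  gapBefore <- c(NA_real_, bursts$onset_s[-1L] - bursts$offset_s[-nb])
  gapAfter <- c(gapBefore[-1L], NA_real_)
  for (i in seq_len(nb)) {
    if (!is.na(gapBefore[i])) {
      w <- if (is.null(tonicWindowS)) 0.5 * gapBefore[i] else tonicWindowS
      w <- min(w, gapBefore[i])
      a <- idxOf(bursts$onset_s[i] - w); b <- idxOf(bursts$onset_s[i])
      src[i] <- "pre"
    } else if (!is.na(gapAfter[i])) {
      w <- if (is.null(tonicWindowS)) 0.5 * gapAfter[i] else tonicWindowS
      w <- min(w, gapAfter[i])
      a <- idxOf(bursts$offset_s[i]); b <- idxOf(bursts$offset_s[i] + w)
      src[i] <- "post"
    } else {
      # single burst: use whatever surrounds it
      a <- 1L; b <- n
      src[i] <- "global"
    }
    tonic[i] <- min(v[a:b])
  }
  data.frame(
    onset_s = bursts$onset_s, offset_s = bursts$offset_s,
    peak_time_s = peakT, peak_amp = peak, tonic = tonic,
    pk_pk = peak - tonic, auc = auc,
    auc_net = auc - tonic * (bursts$offset_s - bursts$onset_s),
    tonic_source = src
  )
}

#' Event rate from inter-onset intervals
#'
#' Rate in events/min computed as `60 / median(inter-onset interval)` over
#' the events whose onsets fall in the window. The median makes the rate
#' robust to occasional missed or split events.
#'
#' @param onsets numeric vector of event onset times, seconds.
#' @param windowS optional `c(start_s, end_s)` window; default all events.
#' @return events/min, or `NA_real_` when fewer than 2 events fall in the
#'   window (undefined rate).
#' @examples
#' eventRate(seq(0, 10, by = 0.4))  # 150 events/min
#' @export
eventRate <- function(onsets, windowS = NULL) {
  if (!is.null(windowS)) {
    onsets <- onsets[onsets >= windowS[1] & onsets < windowS[2]]
  }
  if (length(onsets) < 2L) return(NA_real_)
  60 / median(diff(sort(onsets)))
}

#' Hemodynamic summary of cardiac cycles
#'
#' Window means of per-cycle systolic and diastolic pressure, mean
#' arterial pressure from the standard formula `MAP = DP + (SP - DP)/3`
#' applied to the windowed means, and heart rate as `60 / mean cycle
#' duration`.
#'
#' @param cycles data.frame from [detectCardiacCycles()].
#' @param windowS optional `c(start_s, end_s)` window on cycle starts.
#' @return one-row data.frame `sp`, `dp`, `map`, `hr` (all `NA` when
#'   fewer than 2 cycles fall in the window).
#' @examples
#' hemodynamics(data.frame(start_s = c(0, 0.15), end_s = c(0.15, 0.3),
#'                         sp = 120, dp = 90))
#' @export
hemodynamics <- function(cycles, windowS = NULL) {
  if (!is.null(windowS) && nrow(cycles)) {
    cycles <- cycles[cycles$start_s >= windowS[1] &
                       cycles$start_s < windowS[2], , drop = FALSE]
  }
  if (nrow(cycles) < 2L) {
    return(data.frame(sp = NA_real_, dp = NA_real_, map = NA_real_,
                      hr = NA_real_))
  }
  sp <- mean(cycles$sp)
  dp <- mean(cycles$dp)
  data.frame(sp = sp, dp = dp, map = dp + (sp - dp) / 3,
             hr = 60 / mean(cycles$end_s - cycles$start_s))
}

#' Ventilation summary of detected breaths
#'
#' Mean per-breath Drorbaugh-Fenn tidal volume over the window, normalized
#' to body weight, breathing frequency from [eventRate()], and minute
#' ventilation as their product.
#'
#' @param breaths data.frame from [detectBreaths()] (columns `onset_s`,
#'   `deflection`).
#' @param calib a [PlethCalibration-class] (supplies `bodyMassKg`).
#' @param windowS optional `c(start_s, end_s)` window on breath onsets.
#' @return one-row data.frame: `vt_ml`, `vt_ml_per_kg`, `freq_per_min`,
#'   `ve_ml_per_kg_min`, `n_breaths`. All metrics are `NA` for an empty
#'   window; frequency and minute ventilation are `NA` with fewer than 2
#'   breaths.
#' @export
ventilationSummary <- function(breaths, calib, windowS = NULL) {
  stopifnot(is(calib, "PlethCalibration"))
  if (!is.null(windowS) && nrow(breaths)) {
    breaths <- breaths[breaths$onset_s >= windowS[1] &
                         breaths$onset_s < windowS[2], , drop = FALSE]
  }
  if (!nrow(breaths)) {
    return(data.frame(vt_ml = NA_real_, vt_ml_per_kg = NA_real_,
                      freq_per_min = NA_real_,
                      ve_ml_per_kg_min = NA_real_, n_breaths = 0L))
  }
  vt <- mean(drorbaughFennVt(breaths$deflection, calib))
  vtkg <- vt / calib@bodyMassKg
  freq <- eventRate(breaths$onset_s, windowS)
  data.frame(vt_ml = vt, vt_ml_per_kg = vtkg, freq_per_min = freq,
             ve_ml_per_kg_min = vtkg * freq, n_breaths = nrow(breaths))
}
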