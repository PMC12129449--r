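#' @include signal.R
NULL

#' Detection parameters
#'
#' Bundle of parameters shared by the event detectors. The burst threshold
#' is data-relative: `baseline floor + thresholdK * baseline spread`, where
#' the floor is the median of the quiet (between-burst) portion of the
#' envelope and the spread is a robust (MAD-based) estimate of its SD, so
#' detection is invariant to rescaling the envelope and robust to tonic
#' shifts when baseline statistics are computed per analysis epoch.
#'
#' @param thresholdK threshold height in multiples of the baseline spread
#'   above the baseline floor (default 4; high enough that correlated
#'   fluctuations of the smoothed floor do not produce spurious events).
#' @param minBurstMs minimum event duration, ms; shorter events are
#'   discarded.
#' @param minIntervalMs refractory interval between onsets, ms; events with
#'   closer onsets are merged.
#' @param baselineWindowS seconds of trace used to estimate the noise
#'   floor; `NULL` uses the whole segment passed to the detector.
#' @param onsetRefineFrac after detection, each onset is refined to the
#'   upward crossing of `floor + onsetRefineFrac * (burst peak - floor)`,
#'   which removes the systematic early bias that centered smoothing
#'   imposes on a low threshold crossing; 0 disables refinement.
#' @return A classed list of parameters.
#' @export
detectionParams <- function(thresholdK = 4, minBurstMs = 75,
                            minIntervalMs = 100, baselineWindowS = NULL,
                            onsetRefineFrac = 0.05) {
  stopifnot(thresholdK > 0, minBurstMs > 0, minIntervalMs > 0,
            is.null(baselineWindowS) || baselineWindowS > 0,
            onsetRefineFrac >= 0, onsetRefineFrac < 1)
  structure(list(thresholdK = thresholdK, minBurstMs = minBurstMs,
                 minIntervalMs = minIntervalMs,
                 baselineWindowS = baselineWindowS,
                 onsetRefineFrac = onsetRefineFrac),
            class = "DetectionParams")
}

# Robust floor/spread of an envelope segment: the floor is the median of
# the values at or below the overall median (the quiet fraction when the
# burst duty cycle is < ~50%); the spread is the scaled MAD of that quiet
# fraction.
.floorStats <- function(v) {
  q50 <- median(v)
  lower <- v[v <= q50]
  fl <- median(lower)
  sigma <- mad(lower, center = fl)
  if (sigma == 0) sigma <- mad(v)
  list(floor = fl, sigma = sigma)
}

# Threshold-crossing segmentation with hysteresis shared by the burst and
# breath detectors; returns index-level events.
.segmentAboveThreshold <- function(v, thr, hyst, rate, minBurstMs,
                                   minIntervalMs) {
  above <- v >= thr
  if (!any(above)) return(data.frame(i0 = integer(), i1 = integer()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- starts[r$values]
  belowIdx <- which(v < hyst)
  off <- vapply(on, function(o) {
    j <- findInterval(o, belowIdx) + 1L
    if (j <= length(belowIdx)) belowIdx[j] else length(v)
  }, integer(1))
  # runs swallowed by a previous event's hysteresis window
  keep <- !duplicated(off)
  on <- on[keep]; off <- off[keep]
  if (length(on) > 1L) {
    keep <- c(TRUE, on[-1L] > off[-length(off)])
    on <- on[keep]; off <- off[keep]
  }
  # merge events separated by less than the refractory interval
  if (length(on) > 1L) {
    minGap <- minIntervalMs / 1000 * rate
    gap <- on[-1L] - off[-length(off)]
    grp <- cumsum(c(1L, as.integer(gap >= minGap)))
    on <- tapply(on, grp, min)
    off <- tapply(off, grp, max)
  }
  d <- data.frame(i0 = as.integer(on), i1 = as.integer(off))
  d[(d$i1 - d$i0) / rate * 1000 >= minBurstMs, , drop = FALSE]
}

#' Detect inspiratory bursts in an activity envelope
#'
#' Candidate bursts start at the upward crossing of `floor + thresholdK *
#' spread` (see [detectionParams()]); the offset is the downward crossing
#' of a hysteresis level at 50% of the threshold excess above the floor.
#' Events shorter than `minBurstMs` are discarded, and events whose gap
#' to the preceding event is below `minIntervalMs` are merged (a split
#' burst becomes one event). Finally each onset is refined to the
#' crossing of a small fraction of that burst's amplitude
#' (`onsetRefineFrac`), which centers the reported onset on the true
#' burst start despite the smearing of the centered envelope smoothing.
#' Returned events are strictly time-ordered and non-overlapping.
#'
#' @param env an [Envelope-class] (nonnegative).
#' @param params a [detectionParams()] list.
#' @param baseline optional length-2 numeric `c(start_s, end_s)` window
#'   from which baseline statistics are estimated; default is the first
#'   `baselineWindowS` seconds (or the whole envelope).
#' @return data.frame with columns `onset_s`, `offset_s`, `peak_time_s`.
#' @examples
#' sim <- simulateEmg(simConfig(durationS = 10, seed = 3))
#' env <- signalEnvelope(bandpassFilter(sim$trace, 100, 1000))
#' nrow(detectBursts(env))
#' @export
detectBursts <- function(env, params = detectionParams(), baseline = NULL) {
  stopifnot(is(env, "Envelope"))
  v <- samples(env)
  rate <- samplingRate(env)
  t0 <- startTime(env)
  if (is.null(baseline) && !is.null(params$baselineWindowS)) {
    baseline <- c(t0, t0 + params$baselineWindowS)
  }
  bv <- if (is.null(baseline)) v else {
    i0 <- max(1L, floor((baseline[1] - t0) * rate) + 1L)
    i1 <- min(length(v), ceiling((baseline[2] - t0) * rate))
    if (i1 <= i0) stop("baseline window lies outside the envelope")
    v[i0:i1]
  }
  st <- .floorStats(bv)
  if (st$sigma == 0) {
    warning("degenerate baseline (zero spread); no bursts detected")
    return(data.frame(onset_s = numeric(), offset_s = numeric(),
                      peak_time_s = numeric()))
  }
  thr <- st$floor + params$thresholdK * st$sigma
  hyst <- st$floor + 0.5 * params$thresholdK * st$sigma
  ev <- .segmentAboveThreshold(v, thr, hyst, rate, params$minBurstMs,
                               params$minIntervalMs)
  if (!nrow(ev)) {
    return(data.frame(onset_s = numeric(), offset_s = numeric(),
                      peak_time_s = numeric()))
  }
  peakIdx <- mapply(function(a, b) a - 1L + which.max(v[a:b]), ev$i0, ev$i1)
  frac <- params$onsetRefineFrac
  if (!is.null(frac) && frac > 0) {
    lo <- c(1L, ev$i1[-nrow(ev)])  # never cross into the previous event
    for (j in seq_len(nrow(ev))) {
      L <- st$floor + frac * (v[peakIdx[j]] - st$floor)
      a <- peakIdx[j]
      while (a > lo[j] && v[a - 1L] >= L) a <- a - 1L
      ev$i0[j] <- a
    }
  }
  data.frame(
    onset_s = t0 + (ev$i0 - 1L) / rate,
    offset_s = t0 + (ev$i1 - 1L) / rate,
    peak_time_s = t0 + (peakIdx - 1L) / rate
  )
}

#' Detect breaths in a plethysmograph pressure trace
#'
#' The trace is drift-corrected by subtracting a running median (window
#' `driftWindowS`) and lightly smoothed (`smoothMs`, well below a breath
#' duration) so that broadband noise does not inflate the peak; breaths
#' are segmented where the corrected trace rises above a noise-relative
#' threshold, with 50% hysteresis. The deflection of each breath is its
#' maximum above the corrected baseline (the peak inspiratory deflection
#' feeding [drorbaughFennVt()]).
#'
#' @param trace a [SignalTrace-class] of chamber pressure.
#' @param params a [detectionParams()] list.
#' @param driftWindowS running-median window for drift correction, s.
#' @param smoothMs moving-average window applied before measurement, ms.
#' @return data.frame with `onset_s`, `offset_s`, `deflection`; empty for
#'   an apneic (flat) trace.
#' @export
detectBreaths <- function(trace, params = detectionParams(),
                          driftWindowS = 2, smoothMs = 25) {
  stopifnot(is(trace, "SignalTrace"))
  x <- samples(trace)
  rate <- samplingRate(trace)
  t0 <- startTime(trace)
  if (smoothMs > 0) x <- .movingMeanTrunc(x, .oddWindow(smoothMs, rate))
  k <- .oddWindow(min(driftWindowS, traceDuration(trace) / 2) * 1000, rate)
  z <- x - as.numeric(stats::runmed(x, k, endrule = "median"))
  sigma <- mad(z)
  mx <- max(z)
  if (mx <= 0) {
    return(data.frame(onset_s = numeric(), offset_s = numeric(),
                      deflection = numeric()))
  }
  thr <- if (sigma > 0) params$thresholdK * sigma else 0.05 * mx
  if (thr >= mx) {
    return(data.frame(onset_s = numeric(), offset_s = numeric(),
                      deflection = numeric()))
  }
  ev <- .segmentAboveThreshold(z, thr, 0.5 * thr, rate, params$minBurstMs,
                               params$minIntervalMs)
  if (!nrow(ev)) {
    return(data.frame(onset_s = numeric(), offset_s = numeric(),
                      deflection = numeric()))
  }
  defl <- mapply(function(a, b) max(z[a:b]), ev$i0, ev$i1)
  data.frame(
    onset_s = t0 + (ev$i0 - 1L) / rate,
    offset_s = t0 + (ev$i1 - 1L) / rate,
    deflection = defl
  )
}

#' Detect cardiac cycles in an arterial pressure trace
#'
#' Cycles are delimited by diastolic troughs (local minima of a lightly
#' smoothed trace, at least 40 ms apart and within the lowest quarter of
#' the pressure range); per-cycle systolic pressure is the maximum and
#' diastolic pressure the minimum between consecutive troughs.
#'
#' @param trace a [SignalTrace-class] of arterial pressure.
#' @param smoothMs smoothing window before trough detection, ms.
#' @return data.frame with `start_s`, `end_s`, `sp`, `dp`; empty for a
#'   non-pulsatile trace.
#' @export
detectCardiacCycles <- function(trace, smoothMs = 5) {
  stopifnot(is(trace, "SignalTrace"))
  x <- samples(trace)
  rate <- samplingRate(trace)
  t0 <- startTime(trace)
  rng <- max(x) - min(x)
  empty <- data.frame(start_s = numeric(), end_s = numeric(),
                      sp = numeric(), dp = numeric())
  if (rng == 0 || length(x) < 3L) return(empty)
  xs <- .movingMeanTrunc(x, .oddWindow(smoothMs, rate))
  n <- length(xs)
  cand <- which(xs[2:(n - 1L)] < xs[1:(n - 2L)] &
                  xs[2:(n - 1L)] <= xs[3:n]) + 1L
  cand <- cand[xs[cand] < min(xs) + 0.25 * rng]
  if (length(cand) < 2L) return(empty)
  minDist <- 0.040 * rate
  keep <- cand[1L]
  for (i in cand[-1L]) {
    last <- keep[length(keep)]
    if (i - last >= minDist) {
      keep <- c(keep, i)
    } else if (xs[i] < xs[last]) {
      keep[length(keep)] <- i
    }
  }
  if (length(keep) < 2L) return(empty)
  a <- keep[-length(keep)]
  b <- keep[-1L]
  data.frame(
    start_s = t0 + (a - 1L) / rate,
    end_s = t0 + (b - 1L) / rate,
    sp = mapply(function(i, j) max(x[i:j]), a, b),
    dp = mapply(function(i, j) min(x[i:j]), a, b)
  )
}

#' Quality-control gate for nerve-recording preparations
#'
#' A preparation whose response to a maximal (gasping-like) chemoreceptor
#' challenge is lower than its response to either hypoxic episode shows
#' deteriorating nerve-electrode contact and is excluded from analysis.
#'
#' @param hypoxiaResponses numeric vector of hypoxic response amplitudes
#'   (at least one).
#' @param maximalResponse amplitude of the maximal-challenge response.
#' @return `"include"` or `"exclude"`. Equality is inclusive (the response
#'   must be strictly lower to exclude).
#' @examples
#' qcFlagPreparation(c(2.0, 2.4), 3.0)  # include
#' qcFlagPreparation(c(2.0, 2.4), 2.1)  # exclude
#' @export
qcFlagPreparation <- function(hypoxiaResponses, maximalResponse) {
  if (length(hypoxiaResponses) < 1L || !all(is.finite(hypoxiaResponses))) {
    stop("need at least one finite hypoxia response")
  }
  if (length(maximalResponse) != 1L || !is.finite(maximalResponse)) {
    stop("need a single finite maximal-challenge response")
  }
  if (maximalResponse < max(hypoxiaResponses)) "exclude" else "include"
}
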