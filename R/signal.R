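#' @include AllGenerics.R
NULL

# Zero-phase (forward-backward) Butterworth bandpass with odd-reflection
# padding; signal::filtfilt alone leaves edge transients.
.zeroPhaseBandpass <- function(x, rate, low, high, order = 2) {
  bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  n <- length(x)
  npad <- min(n - 1L, ceiling(3 * rate / low))
  if (npad >= 1L) {
    left <- 2 * x[1L] - x[(npad + 1L):2L]
    right <- 2 * x[n] - x[(n - 1L):(n - npad)]
    y <- signal::filtfilt(bf, c(left, x, right))
    y[(npad + 1L):(npad + n)]
  } else {
    signal::filtfilt(bf, x)
  }
}

# Window width in samples: ms at `rate`, rounded half up, forced odd.
.oddWindow <- function(ms, rate) {
  k <- max(1L, as.integer(floor(ms * rate / 1000 + 0.5)))
  if (k %% 2L == 0L) k <- k + 1L
  k
}

# Centered moving average with window truncation at the edges.
.movingMeanTrunc <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Zero-phase Butterworth bandpass filter
#'
#' Applies a Butterworth bandpass of the given order forward and backward
#' (zero phase), as used for EMG (100--1000 Hz) and phrenic neurogram
#' (100--3000 Hz) preprocessing. Zero-phase filtering preserves burst
#' timing for onset/offset detection; note that the effective magnitude
#' roll-off is doubled relative to a single pass.
#'
#' @param trace a [SignalTrace-class].
#' @param lowHz,highHz band edges, Hz; require
#'   `0 < lowHz < highHz < samplingRate/2`.
#' @param order filter order of each pass (default 2).
#' @return A filtered [SignalTrace-class] of the same length and rate.
#' @examples
#' tr <- SignalTrace(rnorm(5000), 10000)
#' f <- bandpassFilter(tr, 100, 1000)
#' @export
bandpassFilter <- function(trace, lowHz, highHz, order = 2) {
  stopifnot(is(trace, "SignalTrace"))
  rate <- samplingRate(trace)
  if (!(is.finite(lowHz) && is.finite(highHz) && lowHz > 0 &&
        lowHz < highHz && highHz < rate / 2)) {
    stop("invalid band edges: need 0 < lowHz < highHz < samplingRate/2 ",
         "(got lowHz=", lowHz, ", highHz=", highHz, ", rate=", rate, ")")
  }
  y <- .zeroPhaseBandpass(samples(trace), rate, lowHz, highHz, order)
  initialize(trace, samples = y)
}

#' Rectified-integrated envelope
#'
#' Rectifies a signal (absolute value) and smooths it with a centered
#' moving median followed by a centered moving average, yielding a
#' nonnegative activity envelope of the same length and rate. This is the
#' standard "rectify and integrate" step for diaphragm EMG (50 ms median,
#' 50 ms mean in mice; 75 ms median, 175 ms mean in rats) and phrenic
#' neurograms (50 ms / 50 ms). Window widths are converted to odd sample
#' counts (rounding half up) so the windows are symmetric; edges are
#' handled by window truncation.
#'
#' @param trace a [SignalTrace-class] (typically the output of
#'   [bandpassFilter()]).
#' @param medianMs moving-median window width, ms.
#' @param meanMs moving-average window width, ms.
#' @param bandHz optional length-2 band of the preceding filter, recorded
#'   as provenance only.
#' @return An [Envelope-class].
#' @examples
#' tr <- SignalTrace(sin(2 * pi * 300 * seq(0, 1, by = 1e-4)), 10000)
#' env <- signalEnvelope(tr, medianMs = 5, meanMs = 50)
#' @export
signalEnvelope <- function(trace, medianMs = 50, meanMs = 50,
                           bandHz = NULL) {
  stopifnot(is(trace, "SignalTrace"))
  rate <- samplingRate(trace)
  dur <- traceDuration(trace)
  if (!(is.finite(medianMs) && medianMs > 0 && medianMs / 1000 <= dur)) {
    stop("medianMs must be > 0 and no longer than the trace (",
         round(dur * 1000), " ms)")
  }
  if (!(is.finite(meanMs) && meanMs > 0 && meanMs / 1000 <= dur)) {
    stop("meanMs must be > 0 and no longer than the trace (",
         round(dur * 1000), " ms)")
  }
  kMed <- .oddWindow(medianMs, rate)
  kMean <- .oddWindow(meanMs, rate)
  r <- stats::runmed(abs(samples(trace)), kMed, endrule = "median")
  y <- .movingMeanTrunc(as.numeric(r), kMean)
  y[y < 0] <- 0  # guard against floating-point dust
  new("Envelope", samples = y, samplingRate = rate,
      units = traceUnits(trace), channel = channelLabel(trace),
      startTime = startTime(trace),
      smoothing = list(band_hz = bandHz, median_ms = medianMs,
                       mean_ms = meanMs))
}
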