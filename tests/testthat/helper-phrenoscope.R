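# Shared helpers for the suite: an independent analytic oracle for the
# zero-phase Butterworth bandpass, burst matching against ground truth,
# and a tiny Envelope constructor for hand-built cases.

# Amplitude gain of a bilinear-designed digital Butterworth bandpass
# applied forward-backward. Exact for signal::butter: the digital
# response equals the analog prototype evaluated at prewarped
# frequencies, |H|^2 after the two passes.
analyticFiltfiltGain <- function(freqHz, lowHz, highHz, rateHz, order = 2) {
  warp <- function(f) tan(pi * f / rateHz)
  W <- warp(freqHz); W1 <- warp(lowHz); W2 <- warp(highHz)
  X <- (W^2 - W1 * W2) / (W * (W2 - W1))
  (1 / (1 + X^(2 * order)))  # single pass |H| = 1/sqrt(1+X^2n); squared
}

# Measured amplitude of a filtered unit sine, mid-section only (edges
# carry the filter transient).
measureSineGain <- function(freqHz, lowHz, highHz, rateHz, durS = 2) {
  t <- seq(0, durS, by = 1 / rateHz)
  tr <- SignalTrace(sin(2 * pi * freqHz * t), rateHz)
  y <- samples(bandpassFilter(tr, lowHz, highHz))
  mid <- y[floor(length(y) * 0.25):floor(length(y) * 0.75)]
  max(abs(mid))
}

# Match detected bursts to ground truth by nearest onset (within tol);
# returns per-burst relative errors and detection rates.
matchBursts <- function(metrics, truth, tolS = 0.12) {
  mi <- vapply(metrics$onset_s,
               function(o) which.min(abs(truth$onset_s - o)), integer(1))
  ok <- abs(metrics$onset_s - truth$onset_s[mi]) < tolS & !duplicated(mi)
  truePk <- (truth$peak_env - truth$tonic)[mi[ok]]
  list(
    sensitivity = sum(ok) / nrow(truth),
    precision = sum(ok) / nrow(metrics),
    pkErr = (metrics$pk_pk[ok] - truePk) / truePk,
    aucErr = (metrics$auc[ok] - truth$auc[mi[ok]]) / truth$auc[mi[ok]],
    onsetErrS = metrics$onset_s[ok] - truth$onset_s[mi[ok]]
  )
}

# Envelope object from a bare numeric vector (hand-built test cases).
makeEnvelope <- function(v, rate, startTime = 0) {
  new("Envelope", samples = as.numeric(v), samplingRate = rate,
      units = "a.u.", channel = "test", startTime = startTime,
      smoothing = list(band_hz = NULL, median_ms = NA_real_,
                       mean_ms = NA_real_))
}

# Long RM table from a subjects x levels matrix.
rmTable <- function(Y) {
  data.frame(
    subject_id = rep(rownames(Y), times = ncol(Y)),
    epoch = rep(colnames(Y), each = nrow(Y)),
    value = as.vector(Y)
  )
}

# Independent RM-ANOVA F via stats::aov (oracle route).
aovRmF <- function(Y) {
  d <- rmTable(Y)
  d$subject_id <- factor(d$subject_id)
  d$epoch <- factor(d$epoch, levels = unique(d$epoch))
  fit <- summary(stats::aov(value ~ epoch + Error(subject_id / epoch),
                            data = d))
  tb <- fit[["Error: subject_id:epoch"]][[1]]
  list(F = tb$`F value`[1], p = tb$`Pr(>F)`[1], df = tb$Df)
}
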