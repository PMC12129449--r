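#' @include AllGenerics.R
NULL

# Evaluate expr with a local, restored RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Piecewise-linear intervention factor: 1 before onset, ramps to `gain`
# over `ramp` seconds, held to the end of the trace.
.rampFactor <- function(t, gain, onset, ramp) {
  if (ramp <= 0) {
    ifelse(t < onset, 1, gain)
  } else {
    f <- 1 + (gain - 1) * (t - onset) / ramp
    pmin(pmax(f, min(1, gain)), max(1, gain))
  }
}

# Exact integral of .rampFactor over [t1, t2] (antiderivative form).
.rampIntegralF <- function(t, gain, onset, ramp) {
  if (ramp <= 0) ramp <- 0
  a <- onset; b <- onset + ramp
  ifelse(t <= a, t,
    ifelse(t <= b,
      a + (t - a) + (gain - 1) * (t - a)^2 / (2 * max(ramp, .Machine$double.eps)),
      a + ramp + (gain - 1) * ramp / 2 + gain * (t - b)))
}

.rampIntegral <- function(t1, t2, gain, onset, ramp) {
  .rampIntegralF(t2, gain, onset, ramp) - .rampIntegralF(t1, gain, onset, ramp)
}

# Raised-cosine burst envelope on u in [0, 1]: 25% rise, 50% plateau,
# 25% fall. Integrates to 0.75 exactly.
.burstShape <- function(u) {
  s <- numeric(length(u))
  inb <- u >= 0 & u <= 1
  ur <- u[inb]
  s[inb] <- ifelse(ur < 0.25, 0.5 * (1 - cos(pi * ur / 0.25)),
             ifelse(ur <= 0.75, 1,
                    0.5 * (1 - cos(pi * (1 - ur) / 0.25))))
  s
}

.interventionOf <- function(config) {
  iv <- config@intervention
  if (is.null(iv)) {
    list(onset = Inf, ampGain = 1, tonicGain = 1, rateFactor = 1, ramp = 0)
  } else {
    list(onset = iv@onsetS, ampGain = iv@amplitudeGain,
         tonicGain = iv@tonicGain, rateFactor = iv@rateFactor,
         ramp = iv@rampS)
  }
}

# Burst onset times for a config: quasi-periodic with mild lognormal jitter
# of the inter-burst interval; the instantaneous rate follows the
# intervention rate factor. Bursts are truncated at the trace edges (only
# bursts fully inside [0, duration] are kept).
.burstOnsets <- function(config, jitterCv = 0.03) {
  iv <- .interventionOf(config)
  D <- config@burstDurationMs / 1000
  baseInt <- 60 / config@burstRatePerMin
  sdlog <- sqrt(log(1 + jitterCv^2))
  onsets <- numeric(0)
  cur <- 0.5 * baseInt
  while (cur + D <= config@durationS) {
    onsets <- c(onsets, cur)
    jit <- if (jitterCv > 0) exp(rnorm(1, -sdlog^2 / 2, sdlog)) else 1
    cur <- cur + jit * baseInt / .rampFactor(cur, iv$rateFactor,
                                             iv$onset, iv$ramp)
  }
  onsets
}

#' Simulate a diaphragm EMG / phrenic neurogram trace with ground truth
#'
#' Generates a raw-style interference-pattern signal: band-limited Gaussian
#' carrier noise amplitude-modulated by a tonic level plus per-burst
#' raised-cosine envelopes (25% rise, 50% plateau, 25% fall), with additive
#' broadband noise. The carrier is normalized so that the median of its
#' absolute value is 1; the stored ground truth is therefore on the same
#' scale as the rectified-integrated envelope computed by
#' [signalEnvelope()], whose first stage is a moving median.
#'
#' An optional [InterventionSpec-class] models a sustained ligand effect
#' (e.g. DREADD activation): phasic amplitude, tonic level and burst rate
#' are scaled by their gains, ramped linearly over `rampS` seconds from the
#' onset and held to the end of the trace. Ground-truth per-burst AUC is
#' closed form (tonic integral is exact under the piecewise-linear ramp;
#' the raised cosine integrates to 0.75 of its peak times the duration).
#'
#' @param config a [SimConfig-class].
#' @return A list with elements `trace` ([SignalTrace-class]) and `truth`
#'   ([GroundTruth-class] with the `bursts` table filled).
#' @examples
#' sim <- simulateEmg(simConfig(durationS = 5, seed = 42))
#' head(truthBursts(sim$truth))
#' @seealso [modulationEnvelope()] for the noiseless envelope,
#'   [simulateCohort()] for multi-subject designs.
#' @export
simulateEmg <- function(config) {
  validObject(config)
  .withSeed(config@seed, {
    rate <- config@samplingRateHz
    n <- round(config@durationS * rate)
    t <- (seq_len(n) - 1L) / rate
    iv <- .interventionOf(config)
    D <- config@burstDurationMs / 1000

    onsets <- .burstOnsets(config)
    amps <- config@phasicAmplitude *
      .rampFactor(onsets + D / 2, iv$ampGain, iv$onset, iv$ramp)

    m <- config@tonicLevel *
      .rampFactor(t, iv$tonicGain, iv$onset, iv$ramp)
    for (i in seq_along(onsets)) {
      i0 <- max(1L, floor(onsets[i] * rate) + 1L)
      i1 <- min(n, ceiling((onsets[i] + D) * rate) + 1L)
      idx <- i0:i1
      m[idx] <- m[idx] + amps[i] * .burstShape((t[idx] - onsets[i]) / D)
    }

    carrier <- .zeroPhaseBandpass(rnorm(n), rate,
                                  config@carrierBandHz[1],
                                  config@carrierBandHz[2], order = 2)
    med <- median(abs(carrier))
    if (med > 0) carrier <- carrier / med
    x <- carrier * m
    if (config@noiseFloor > 0) x <- x + rnorm(n, sd = config@noiseFloor)

    tonicAt <- function(tt) {
      config@tonicLevel * .rampFactor(tt, iv$tonicGain, iv$onset, iv$ramp)
    }
    offsets <- onsets + D
    auc <- config@tonicLevel *
      .rampIntegral(onsets, offsets, iv$tonicGain, iv$onset, iv$ramp) +
      amps * 0.75 * D
    bursts <- data.frame(
      onset_s = onsets, offset_s = offsets, peak_time_s = onsets + D / 2,
      peak_env = tonicAt(onsets + D / 2) + amps,
      tonic = tonicAt(onsets), amplitude = amps, auc = auc
    )
    list(
      trace = SignalTrace(x, rate, units = "a.u.", channel = "emg_sim"),
      truth = new("GroundTruth", bursts = bursts)
    )
  })
}

#' Noiseless modulation envelope of a simulated EMG trace
#'
#' Reconstructs the exact (noise-free) modulation envelope `tonic(t) +
#' sum_i amplitude_i * shape((t - onset_i)/duration)` for a simulation,
#' from its config and stored ground truth. Numerically integrating this
#' envelope over each burst window reproduces the stored per-burst AUC.
#'
#' @param config the [SimConfig-class] used for the simulation.
#' @param truth the matching [GroundTruth-class].
#' @return A [SignalTrace-class] holding the envelope.
#' @export
modulationEnvelope <- function(config, truth) {
  rate <- config@samplingRateHz
  n <- round(config@durationS * rate)
  t <- (seq_len(n) - 1L) / rate
  iv <- .interventionOf(config)
  m <- config@tonicLevel * .rampFactor(t, iv$tonicGain, iv$onset, iv$ramp)
  b <- truthBursts(truth)
  for (i in seq_len(nrow(b))) {
    D <- b$offset_s[i] - b$onset_s[i]
    i0 <- max(1L, floor(b$onset_s[i] * rate) + 1L)
    i1 <- min(n, ceiling(b$offset_s[i] * rate) + 1L)
    idx <- i0:i1
    m[idx] <- m[idx] + b$amplitude[i] * .burstShape((t[idx] - b$onset_s[i]) / D)
  }
  SignalTrace(m, rate, units = "a.u.", channel = "envelope_truth")
}

#' Simulate a pulsatile arterial-pressure trace with ground truth
#'
#' Each cardiac cycle is `dp + (sp - dp) * sin(pi * phase)^2`, so the
#' per-cycle maximum and minimum equal the requested systolic and diastolic
#' pressures before noise. Ground-truth beat times are independent of the
#' added noise.
#'
#' @param durationS trace duration, seconds.
#' @param samplingRateHz sampling rate, samples/s.
#' @param heartRateBpm heart rate, beats/min.
#' @param sp,dp systolic and diastolic pressure, mmHg (`sp > dp > 0`).
#' @param noiseSd additive Gaussian noise SD, mmHg.
#' @param seed integer RNG seed.
#' @return list(trace = [SignalTrace-class], truth = [GroundTruth-class]
#'   with the `beats` table filled); only complete cycles are listed.
#' @export
simulateArterialPressure <- function(durationS, samplingRateHz = 1000,
                                     heartRateBpm = 400, sp = 120, dp = 90,
                                     noiseSd = 0, seed = 1L) {
  if (!is.finite(durationS) || durationS <= 0) {
    stop("durationS must be > 0")
  }
  if (!is.finite(heartRateBpm) || heartRateBpm <= 0) {
    stop("heartRateBpm must be > 0")
  }
  if (!(sp > dp && dp > 0)) {
    stop("invalid pressures: need sp > dp > 0 (got sp=", sp, ", dp=", dp, ")")
  }
  .withSeed(seed, {
    rate <- samplingRateHz
    n <- round(durationS * rate)
    t <- (seq_len(n) - 1L) / rate
    period <- 60 / heartRateBpm
    phase <- (t %% period) / period
    x <- dp + (sp - dp) * sin(pi * phase)^2
    if (noiseSd > 0) x <- x + rnorm(n, sd = noiseSd)
    nBeats <- floor(durationS / period + 1e-9)
    beats <- data.frame(
      start_s = (seq_len(nBeats) - 1L) * period,
      end_s = seq_len(nBeats) * period,
      sp = rep(sp, nBeats), dp = rep(dp, nBeats)
    )
    list(
      trace = SignalTrace(x, rate, units = "mmHg", channel = "abp_sim"),
      truth = new("GroundTruth", beats = beats)
    )
  })
}

#' Simulate a barometric plethysmograph trace with ground truth
#'
#' Chamber-pressure deflections are computed by inverting the
#' Drorbaugh-Fenn equation: for the requested tidal volume and calibration,
#' the peak inspiratory deflection is `PT = VT * PK / (VK * factor)` where
#' `factor` is the Drorbaugh-Fenn correction (see [drorbaughFennVt()]), so
#' the analysis pipeline should recover the generating volume. Each breath
#' is a half-sine deflection occupying 40% of the breath period.
#'
#' @param durationS trace duration, seconds.
#' @param samplingRateHz sampling rate, samples/s.
#' @param breathRatePerMin breathing rate, breaths/min.
#' @param trueVtMl tidal volume to encode, ml (0 gives a flat trace).
#' @param calib a [PlethCalibration-class].
#' @param noiseSd additive Gaussian noise SD, pressure units.
#' @param seed integer RNG seed.
#' @param intervention optional [InterventionSpec-class]: `amplitudeGain`
#'   scales tidal volume, `rateFactor` scales breath rate from its onset.
#' @return list(trace = [SignalTrace-class], truth = [GroundTruth-class]
#'   with the `breaths` table filled).
#' @export
simulatePleth <- function(durationS, samplingRateHz = 1000,
                          breathRatePerMin = 100, trueVtMl = 2,
                          calib = plethCalibration(), noiseSd = 0,
                          seed = 1L, intervention = NULL) {
  if (!is.finite(durationS) || durationS <= 0) stop("durationS must be > 0")
  if (!is.finite(breathRatePerMin) || breathRatePerMin <= 0) {
    stop("breathRatePerMin must be > 0")
  }
  if (trueVtMl < 0) stop("trueVtMl must be >= 0")
  validObject(calib)
  iv <- if (is.null(intervention)) {
    list(onset = Inf, ampGain = 1, tonicGain = 1, rateFactor = 1, ramp = 0)
  } else {
    list(onset = intervention@onsetS, ampGain = intervention@amplitudeGain,
         tonicGain = intervention@tonicGain,
         rateFactor = intervention@rateFactor, ramp = intervention@rampS)
  }
  .withSeed(seed, {
    rate <- samplingRateHz
    n <- round(durationS * rate)
    t <- (seq_len(n) - 1L) / rate
    x <- numeric(n)
    ptPerMl <- calib@pkDefl / (calib@vkMl * .dfFactor(calib))

    onsets <- numeric(0); vts <- numeric(0); tis <- numeric(0)
    cur <- 0.25 * 60 / breathRatePerMin
    repeat {
      period <- 60 / (breathRatePerMin *
                        .rampFactor(cur, iv$rateFactor, iv$onset, iv$ramp))
      ti <- 0.4 * period
      if (cur + ti > durationS) break
      onsets <- c(onsets, cur); tis <- c(tis, ti)
      vts <- c(vts, trueVtMl * .rampFactor(cur, iv$ampGain, iv$onset,
                                           iv$ramp))
      cur <- cur + period
    }
    pts <- vts * ptPerMl
    for (i in seq_along(onsets)) {
      i0 <- max(1L, floor(onsets[i] * rate) + 1L)
      i1 <- min(n, ceiling((onsets[i] + tis[i]) * rate) + 1L)
      idx <- i0:i1
      u <- (t[idx] - onsets[i]) / tis[i]
      w <- u >= 0 & u <= 1
      x[idx[w]] <- x[idx[w]] + pts[i] * sin(pi * u[w])
    }
    if (noiseSd > 0) x <- x + rnorm(n, sd = noiseSd)
    breaths <- data.frame(
      onset_s = onsets, offset_s = onsets + tis,
      deflection = pts, vt_ml = vts
    )
    list(
      trace = SignalTrace(x, rate, units = "pressure", channel = "pleth_sim"),
      truth = new("GroundTruth", breaths = breaths)
    )
  })
}

#' Simulate a cohort of subjects with inter-subject variability
#'
#' Derives one deterministic sub-seed per subject from the master seed and
#' applies log-normal inter-subject multipliers (unit mean, coefficient of
#' variation `cv`) to the phasic/tonic amplitudes and to the burst rate.
#' With `cv = 0` every subject shares identical simulation parameters (the
#' per-subject carrier noise still differs through the sub-seed).
#'
#' @param nSubjects number of subjects (>= 1).
#' @param config baseline [SimConfig-class] shared by the cohort.
#' @param cv coefficient of variation of the inter-subject multipliers.
#' @param seed master integer seed.
#' @param cohort cohort label recorded in the metadata.
#' @return list with `subjects` (a list of per-subject lists: `id`,
#'   `config`, `trace`, `truth`) and `metadata` (data.frame: subject_id,
#'   cohort, amp_mult, rate_mult, seed).
#' @examples
#' coh <- simulateCohort(3, simConfig(durationS = 2), cv = 0.1, seed = 9)
#' coh$metadata
#' @export
simulateCohort <- function(nSubjects, config, cv = 0, seed = 1L,
                           cohort = "cohort") {
  if (!is.finite(nSubjects) || nSubjects < 1) stop("nSubjects must be >= 1")
  validObject(config)
  nSubjects <- as.integer(nSubjects)
  mult <- .withSeed(seed, {
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      matrix(exp(rnorm(2L * nSubjects, -sdlog^2 / 2, sdlog)),
             ncol = 2L)
    } else {
      matrix(1, nSubjects, 2L)
    }
  })
  subSeeds <- (as.integer(seed) + 1009L * seq_len(nSubjects)) %%
    .Machine$integer.max
  subjects <- vector("list", nSubjects)
  for (i in seq_len(nSubjects)) {
    cfg <- config
    cfg@phasicAmplitude <- config@phasicAmplitude * mult[i, 1L]
    cfg@tonicLevel <- config@tonicLevel * mult[i, 1L]
    cfg@burstRatePerMin <- config@burstRatePerMin * mult[i, 2L]
    cfg@seed <- as.integer(subSeeds[i])
    sim <- simulateEmg(cfg)
    subjects[[i]] <- list(id = sprintf("S%02d", i), config = cfg,
                          trace = sim$trace, truth = sim$truth)
  }
  metadata <- data.frame(
    subject_id = vapply(subjects, `[[`, "", "id"),
    cohort = cohort,
    amp_mult = mult[, 1L], rate_mult = mult[, 2L],
    seed = as.integer(subSeeds)
  )
  list(subjects = subjects, metadata = metadata)
}
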