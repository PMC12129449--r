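#' @include stats.R io.R
NULL

# Sub-trace on [t0, t1) keeping class, rate and absolute start time.
.sliceTrace <- function(x, t0, t1) {
  rate <- samplingRate(x)
  s0 <- startTime(x)
  i0 <- max(1L, floor((t0 - s0) * rate) + 1L)
  i1 <- min(nSamples(x), ceiling((t1 - s0) * rate))
  if (i1 <= i0) stop("empty trace slice [", t0, ", ", t1, ")")
  initialize(x, samples = samples(x)[i0:i1],
             startTime = s0 + (i0 - 1L) / rate)
}

.fillConfig <- function(defaults, config) {
  utils::modifyList(defaults, config)
}

#' Default configuration for an EMG study run
#'
#' Returns the default desk-scale configuration used by [runEmgStudy()]
#' and [runPhrenicStudy()]: a time-scaled version of the full protocol
#' (scale 1/60 gives a 120-s mouse protocol) with a moderate cohort and
#' the generator defaults of [simConfig()]. Any field can be overridden
#' via `...`.
#'
#' @param ... named overrides merged into the default list.
#' @return configuration list.
#' @export
emgStudyConfig <- function(...) {
  .fillConfig(list(
    protocol = "mouse_emg",
    scale = 1 / 60,
    timeline = NULL,
    nSubjects = 6L,
    sides = c("left", "right"),
    cohort = "chat_cre",
    cv = 0.2,
    amplitudeGain = 2.5, tonicGain = 1.5, rateFactor = 1, rampS = 5,
    samplingRateHz = 2000, carrierBandHz = c(100, 500),
    burstRatePerMin = 90, burstDurationMs = 180,
    phasicAmplitude = 1, tonicLevel = 0.15, noiseFloor = 0.05,
    band = c(100, 500),
    envelope = list(medianMs = 50, meanMs = 50),
    detection = list(thresholdK = 4, minBurstMs = 75,
                     minIntervalMs = 100),
    summaryWindowS = 10,
    baselineLabel = "BL",
    deaths = NULL,
    qcResponses = NULL,
    seed = 1L,
    outputDir = NULL
  ), list(...))
}

#' Detect and quantify bursts epoch by epoch
#'
#' Runs [detectBursts()] and [burstMetrics()] separately inside every
#' epoch of a timeline, re-estimating the baseline floor and threshold
#' within each epoch. This is the recommended pattern when the tonic
#' level drifts across the recording (e.g. a sustained tonic increase
#' after a ligand): a single global threshold ends up inside the shifted
#' between-burst floor and merges or misses events, while a per-epoch
#' threshold follows the floor.
#'
#' @param env an [Envelope-class] spanning the timeline.
#' @param timeline a timeline data.frame ([protocolTimeline()] or
#'   [makeTimeline()]).
#' @param params a [detectionParams()] list.
#' @param tonicWindowS tonic window passed to [burstMetrics()].
#' @return data.frame of per-burst metrics with absolute times.
#' @export
epochBurstMetrics <- function(env, timeline, params = detectionParams(),
                              tonicWindowS = 0.075) {
  timeline <- .validateTimeline(timeline)
  out <- list()
  for (i in seq_len(nrow(timeline))) {
    sl <- .sliceTrace(env, timeline$start_s[i], timeline$end_s[i])
    ev <- suppressWarnings(detectBursts(sl, params))
    if (nrow(ev)) out[[i]] <- burstMetrics(sl, ev, tonicWindowS)
  }
  if (!length(out)) {
    return(burstMetrics(env, data.frame()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.detectByEpoch <- function(env, timeline, detection) {
  epochBurstMetrics(env, timeline, do.call(detectionParams, detection))
}

.emgSimConfigOf <- function(config, duration, j60Onset) {
  iv <- NULL
  if (is.finite(j60Onset)) {
    iv <- interventionSpec(j60Onset,
                           amplitudeGain = config$amplitudeGain,
                           tonicGain = config$tonicGain,
                           rateFactor = config$rateFactor,
                           rampS = config$rampS)
  }
  simConfig(durationS = duration,
            samplingRateHz = config$samplingRateHz,
            burstRatePerMin = config$burstRatePerMin,
            burstDurationMs = config$burstDurationMs,
            phasicAmplitude = config$phasicAmplitude,
            tonicLevel = config$tonicLevel,
            carrierBandHz = config$carrierBandHz,
            noiseFloor = config$noiseFloor,
            intervention = iv, seed = config$seed)
}

.studyStats <- function(table, metrics, baselineLabel) {
  stats <- list()
  for (side in unique(table$side)) {
    for (m in metrics) {
      sub <- table[table$side == side & table$metric == m &
                     !is.na(table$value), , drop = FALSE]
      if (length(unique(sub$epoch)) < 2L ||
          length(unique(sub$subject_id)) < 2L) next
      res <- tryCatch(oneWayRmAnovaAuto(sub, value = "value"),
                      error = function(e) NULL)
      if (is.null(res)) next
      if (!is.na(pValue(res)) && pValue(res) <= 0.05 &&
          res@testName == "one-way RM-ANOVA") {
        res@postHoc <- tukeyHsd(res)
        res@correction <- "Tukey"
      }
      stats[[paste(side, m, sep = ".")]] <- res
    }
  }
  stats
}

.writeBundle <- function(outputDir, config, events, table, stats) {
  if (is.null(outputDir)) return(invisible(NULL))
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(events, file.path(outputDir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(table, file.path(outputDir, "cohort_table.csv"),
                   row.names = FALSE)
  rpt <- file(file.path(outputDir, "stats_report.txt"), "w")
  for (nm in names(stats)) {
    writeLines(paste0("== ", nm, " =="), rpt)
    out <- utils::capture.output(show(stats[[nm]]))
    writeLines(out, rpt)
    writeLines("", rpt)
  }
  close(rpt)
  .writeManifest(config, file.path(outputDir, "manifest.json"))
  invisible(outputDir)
}

#' Run a simulated diaphragm EMG study end to end
#'
#' Simulates a cohort of subjects (left and right hemidiaphragm channels)
#' under the mouse EMG protocol with a sustained ligand intervention,
#' processes every trace through the full analysis chain (bandpass
#' filter, rectified-integrated envelope, per-epoch burst detection,
#' per-burst metrics), assembles the baseline-normalized cohort table
#' (censoring deaths if given), and applies the statistical battery
#' (one-way repeated-measures ANOVA across epochs per side and metric,
#' with the assumption gate and Tukey post hoc).
#'
#' @param config configuration list from [emgStudyConfig()] or a path to
#'   a YAML file with the same fields.
#' @return (invisibly) a list: `timeline`, `events`, `table` (long cohort
#'   table with `value_pct_baseline`), `stats` (named [TestResult-class]
#'   list), `normalizedMeans` (mean percent-of-baseline per side, epoch
#'   and metric), `config`. When `config$outputDir` is set, the bundle
#'   (events.csv, cohort_table.csv, stats_report.txt, manifest.json) is
#'   written there.
#' @examples
#' res <- suppressMessages(runEmgStudy(emgStudyConfig(
#'   nSubjects = 3, sides = "left", scale = 1 / 120, seed = 7)))
#' head(res$normalizedMeans)
#' @export
runEmgStudy <- function(config = emgStudyConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- .fillConfig(emgStudyConfig(), config)
  if (!length(config$sides)) stop("configuration error: empty channel list")
  timeline <- if (!is.null(config$timeline)) {
    .validateTimeline(config$timeline)
  } else {
    protocolTimeline(config$protocol, config$scale)
  }
  duration <- max(timeline$end_s)
  j60 <- grepl("^J60", timeline$label)
  j60Onset <- if (any(j60)) min(timeline$start_s[j60]) else Inf

  metrics <- c("pk_pk", "auc", "tonic", "peak_amp")
  events <- list(); rows <- list()
  for (j in seq_along(config$sides)) {
    side <- config$sides[j]
    cfg <- .emgSimConfigOf(config, duration, j60Onset)
    cfg@seed <- as.integer((config$seed + 500009L * (j - 1L)) %%
                             .Machine$integer.max)
    coh <- simulateCohort(config$nSubjects, cfg, cv = config$cv,
                          seed = cfg@seed, cohort = config$cohort)
    for (s in coh$subjects) {
      filt <- bandpassFilter(s$trace, config$band[1], config$band[2])
      env <- signalEnvelope(filt, config$envelope$medianMs,
                            config$envelope$meanMs,
                            bandHz = config$band)
      met <- .detectByEpoch(env, timeline, config$detection)
      if (!nrow(met)) next
      met$subject_id <- s$id; met$side <- side
      events[[paste(side, s$id)]] <- met
      lab <- assignEpochs(timeline, met)
      summ <- summarizeEpoch(lab, timeline, metrics = metrics,
                             summaryWindowS = config$summaryWindowS)
      summ$subject_id <- s$id
      summ$side <- side
      summ$cohort <- config$cohort
      rows[[paste(side, s$id)]] <- summ
    }
  }
  events <- do.call(rbind, events)
  table <- do.call(rbind, rows)
  rownames(events) <- rownames(table) <- NULL
  table <- addBaselineNormalization(table, config$baselineLabel)
  if (!is.null(config$deaths)) {
    for (i in seq_len(nrow(config$deaths))) {
      table <- censorDeath(config$deaths[i, ], table)
    }
  }
  stats <- .studyStats(table, c(metrics, "event_rate"),
                       config$baselineLabel)
  nm <- aggregate(value_pct_baseline ~ side + epoch + metric,
                  data = table, FUN = mean, na.rm = TRUE)
  .writeBundle(config$outputDir, config, events, table, stats)
  invisible(list(timeline = timeline, events = events, table = table,
                 stats = stats, normalizedMeans = nm, config = config))
}

#' Default configuration for a plethysmography study run
#'
#' @param ... named overrides.
#' @return configuration list for [runPlethStudy()]: session layout
#'   (baseline then time bins, both treatments per subject), breathing
#'   and tidal-volume parameters, ligand effect on tidal volume
#'   (`vtGain`), chamber calibration and detection settings.
#' @export
plethStudyConfig <- function(...) {
  .fillConfig(list(
    nSubjects = 6L,
    cohort = "chat_cre_rat",
    sessionBaselineS = 60, binS = 30, nBins = 3L,
    samplingRateHz = 500,
    breathRatePerMin = 100, trueVtMl = 2.0,
    vtGain = 1.2, rateGain = 1, rampS = 5,
    noiseSd = 0.005,
    calib = plethCalibration(vkMl = 1, pkDefl = 0.5, bodyMassKg = 0.35),
    detection = list(thresholdK = 4, minBurstMs = 40,
                     minIntervalMs = 150),
    seed = 1L,
    outputDir = NULL
  ), list(...))
}

#' Run a simulated whole-body plethysmography study end to end
#'
#' Each subject contributes one vehicle (saline) and one ligand session:
#' a baseline period followed by post-infusion time bins. Traces are
#' generated by inverting the Drorbaugh-Fenn equation, breaths are
#' detected on the drift-corrected chamber pressure, and tidal volume,
#' breathing frequency and minute ventilation are summarized per bin. The
#' treatment-by-time comparison uses the two-way repeated-measures ANOVA
#' on raw and baseline-normalized metrics.
#'
#' @param config configuration list from [plethStudyConfig()] or a YAML
#'   path.
#' @return (invisibly) list: `timeline`, `table`, `stats`, `config`.
#' @export
runPlethStudy <- function(config = plethStudyConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- .fillConfig(plethStudyConfig(), config)
  calib <- config$calib
  if (!is(calib, "PlethCalibration")) {
    stop("configuration error: missing or invalid plethysmograph ",
         "calibration (config$calib)")
  }
  validObject(calib)
  nb <- config$nBins
  timeline <- makeTimeline(
    c("BL", sprintf("T%d", seq_len(nb))),
    c(0, config$sessionBaselineS + (seq_len(nb) - 1L) * config$binS),
    c(config$sessionBaselineS, config$sessionBaselineS +
        seq_len(nb) * config$binS),
    protocolId = "rat_pleth_session")
  duration <- max(timeline$end_s)
  params <- do.call(detectionParams, config$detection)

  rows <- list()
  for (i in seq_len(config$nSubjects)) {
    for (treatment in c("SL", "J60")) {
      iv <- if (treatment == "J60") {
        interventionSpec(config$sessionBaselineS,
                         amplitudeGain = config$vtGain,
                         rateFactor = config$rateGain,
                         rampS = config$rampS)
      } else NULL
      seed <- (config$seed + 1009L * i +
                 500009L * (treatment == "J60")) %% .Machine$integer.max
      sim <- simulatePleth(duration, config$samplingRateHz,
                           config$breathRatePerMin, config$trueVtMl,
                           calib, noiseSd = config$noiseSd,
                           seed = seed, intervention = iv)
      breaths <- detectBreaths(sim$trace, params)
      for (e in seq_len(nrow(timeline))) {
        vs <- ventilationSummary(breaths, calib,
                                 c(timeline$start_s[e],
                                   timeline$end_s[e]))
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("R%02d", i), cohort = config$cohort,
          treatment = treatment, epoch = timeline$label[e],
          epoch_start_s = timeline$start_s[e],
          metric = c("vt_ml", "vt_ml_per_kg", "freq_per_min",
                     "ve_ml_per_kg_min"),
          value = c(vs$vt_ml, vs$vt_ml_per_kg, vs$freq_per_min,
                    vs$ve_ml_per_kg_min),
          side = "n/a"
        )
      }
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  # normalize within subject x treatment x metric to the session baseline
  table$side <- table$treatment  # reuse side key for normalization
  table <- addBaselineNormalization(table, "BL")
  table$side <- "n/a"

  stats <- list()
  for (m in c("vt_ml", "freq_per_min", "ve_ml_per_kg_min")) {
    sub <- table[table$metric == m & !is.na(table$value), , drop = FALSE]
    stats[[m]] <- tryCatch(
      twoWayRmAnova(sub, factors = c("treatment", "epoch")),
      error = function(e) NULL)
    subn <- sub[!is.na(sub$value_pct_baseline), , drop = FALSE]
    stats[[paste0(m, ".pct")]] <- tryCatch(
      twoWayRmAnova(subn, factors = c("treatment", "epoch"),
                    value = "value_pct_baseline"),
      error = function(e) NULL)
  }
  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(table,
                     file.path(config$outputDir, "cohort_table.csv"),
                     row.names = FALSE)
    .writeManifest(config, file.path(config$outputDir, "manifest.json"))
  }
  invisible(list(timeline = timeline, table = table, stats = stats,
                 config = config))
}

#' Run a simulated phrenic nerve study end to end
#'
#' Like [runEmgStudy()] but for the phrenic neurogram protocol: bilateral
#' nerve channels plus an arterial-pressure channel per subject. The
#' preparation quality-control gate ([qcFlagPreparation()]) is applied
#' before statistics when `config$qcResponses` supplies per-subject
#' hypoxic and maximal-challenge response amplitudes; excluded subjects
#' are removed from the cohort table. Hemodynamics (SP, DP, MAP, HR) are
#' summarized per epoch from detected cardiac cycles; if the pressure
#' channel is disabled (`includePressure = FALSE`) hemodynamics are
#' skipped with a warning and burst analysis proceeds.
#'
#' @param config configuration list (fields of [emgStudyConfig()] plus
#'   `heartRateBpm`, `sp`, `dp`, `bpNoiseSd`, `includePressure`) or a
#'   YAML path.
#' @return (invisibly) list as [runEmgStudy()] plus `qc` (per-subject
#'   include/exclude decisions).
#' @export
runPhrenicStudy <- function(config = list()) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- .fillConfig(emgStudyConfig(
    protocol = "rat_phrenic", scale = 1 / 60,
    cohort = "chat_cre_rat",
    heartRateBpm = 400, sp = 120, dp = 90, bpNoiseSd = 1,
    includePressure = TRUE,
    envelope = list(medianMs = 50, meanMs = 50)
  ), config)

  res <- runEmgStudy(.fillConfig(config, list(outputDir = NULL)))
  table <- res$table

  # preparation QC gate
  qc <- NULL
  if (!is.null(config$qcResponses)) {
    qc <- do.call(rbind, lapply(names(config$qcResponses), function(sid) {
      r <- config$qcResponses[[sid]]
      data.frame(subject_id = sid,
                 decision = qcFlagPreparation(r$hypoxia, r$maximal))
    }))
    excl <- qc$subject_id[qc$decision == "exclude"]
    if (length(excl)) {
      message("QC: excluding preparation(s) ",
              paste(excl, collapse = ", "),
              " (maximal challenge below hypoxic response)")
      table <- table[!table$subject_id %in% excl, , drop = FALSE]
    }
  }

  # hemodynamics per subject from the arterial channel
  if (isTRUE(config$includePressure)) {
    duration <- max(res$timeline$end_s)
    hrows <- list()
    for (i in seq_len(config$nSubjects)) {
      sid <- sprintf("S%02d", i)
      if (!is.null(qc) && sid %in% qc$subject_id[qc$decision == "exclude"])
        next
      sim <- simulateArterialPressure(
        duration, samplingRateHz = 500,
        heartRateBpm = config$heartRateBpm, sp = config$sp,
        dp = config$dp, noiseSd = config$bpNoiseSd,
        seed = (config$seed + 7717L * i) %% .Machine$integer.max)
      cycles <- detectCardiacCycles(sim$trace)
      for (e in seq_len(nrow(res$timeline))) {
        w <- c(max(res$timeline$start_s[e],
                   res$timeline$end_s[e] - config$summaryWindowS),
               res$timeline$end_s[e])
        h <- hemodynamics(cycles, w)
        hrows[[length(hrows) + 1L]] <- data.frame(
          epoch = res$timeline$label[e],
          epoch_start_s = res$timeline$start_s[e],
          metric = c("sp", "dp", "map", "hr"),
          value = c(h$sp, h$dp, h$map, h$hr),
          n_events = NA_integer_, subject_id = sid,
          side = "n/a", cohort = config$cohort,
          value_pct_baseline = NA_real_)
      }
    }
    table <- rbind(table, do.call(rbind, hrows))
    rownames(table) <- NULL
  } else {
    warning("blood-pressure channel absent: hemodynamics skipped")
  }

  stats <- .studyStats(table,
                       c("pk_pk", "auc", "tonic", "event_rate",
                         "sp", "dp", "map", "hr"),
                       config$baselineLabel)
  nm <- aggregate(value_pct_baseline ~ side + epoch + metric,
                  data = table[!is.na(table$value_pct_baseline), ],
                  FUN = mean, na.rm = TRUE)
  .writeBundle(config$outputDir, config,
               res$events[res$events$subject_id %in%
                            unique(table$subject_id), , drop = FALSE],
               table, stats)
  invisible(list(timeline = res$timeline, events = res$events,
                 table = table, stats = stats, normalizedMeans = nm,
                 qc = qc, config = config))
}
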