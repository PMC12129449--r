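test_that("EMG study runs are deterministic under a fixed seed", {
  cfg <- emgStudyConfig(nSubjects = 3L, sides = "left", scale = 1 / 120,
                        summaryWindowS = 5, seed = 31L)
  a <- suppressMessages(runEmgStudy(cfg))
  b <- suppressMessages(runEmgStudy(cfg))
  expect_identical(a$table, b$table)
  expect_error(runEmgStudy(emgStudyConfig(sides = character())),
               "empty channel")
})

test_that("a gain-2 intervention doubles normalized amplitude cohort-wide", {
  cfg <- emgStudyConfig(nSubjects = 4L, sides = "left", cv = 0,
                        amplitudeGain = 2, tonicGain = 1.5, seed = 5L)
  res <- suppressMessages(runEmgStudy(cfg))
  nm <- res$normalizedMeans
  post <- nm$value_pct_baseline[nm$metric == "pk_pk" &
                                  nm$epoch == "J60_90"]
  expect_lt(abs(post - 200), 8)
  p <- pValue(res$stats[["left.pk_pk"]])
  expect_lt(p, 0.05)
})

test_that("death censoring propagates into the cohort table", {
  tl <- protocolTimeline("mouse_emg", scale = 1 / 60)
  deaths <- data.frame(subject_id = "S02",
                       death_time_s = tl$start_s[tl$label == "J60_60"])
  cfg <- emgStudyConfig(nSubjects = 3L, sides = "left", scale = 1 / 60,
                        deaths = deaths, seed = 8L)
  res <- suppressMessages(runEmgStudy(cfg))
  s2 <- res$table[res$table$subject_id == "S02", ]
  expect_false(any(s2$epoch %in% c("J60_60", "J60_90")))
  expect_true(all(c("BL", "SL", "J60_30") %in% s2$epoch))
  expect_setequal(unique(res$table$epoch[res$table$subject_id == "S01"]),
                  c("BL", "SL", "J60_30", "J60_60", "J60_90"))
})

test_that("pleth study recovers generated tidal volume and runs the ANOVA", {
  cfg <- plethStudyConfig(nSubjects = 4L, sessionBaselineS = 30,
                          binS = 20, nBins = 2L, vtGain = 1, seed = 3L)
  res <- suppressMessages(runPlethStudy(cfg))
  vt <- res$table$value[res$table$metric == "vt_ml"]
  expect_lt(abs(mean(vt) / cfg$trueVtMl - 1), 0.02)
  expect_true(!is.null(res$stats$vt_ml))
  expect_true(all(c("treatment", "epoch") %in%
                    effectsTable(res$stats$vt_ml)$effect))
  expect_error(suppressMessages(
    runPlethStudy(plethStudyConfig(calib = "missing"))), "calibration")
})

test_that("phrenic study applies the QC gate and handles missing pressure", {
  qc <- list(
    S01 = list(hypoxia = c(2.0, 2.4), maximal = 3.0),
    S02 = list(hypoxia = c(2.0, 2.4), maximal = 2.1)  # deteriorating
  )
  cfg <- list(nSubjects = 3L, sides = "left", scale = 1 / 120,
              summaryWindowS = 5, qcResponses = qc, seed = 2L)
  res <- suppressMessages(runPhrenicStudy(cfg))
  expect_identical(res$qc$decision[res$qc$subject_id == "S02"], "exclude")
  expect_false("S02" %in% res$table$subject_id)
  expect_true("S01" %in% res$table$subject_id)
  expect_true(any(res$table$metric == "map"))
  h <- res$table[res$table$metric == "map" & !is.na(res$table$value), ]
  expect_true(all(h$value > 90 & h$value < 120))

  cfg$includePressure <- FALSE
  expect_warning(res2 <- suppressMessages(runPhrenicStudy(cfg)),
                 "hemodynamics skipped")
  expect_false(any(res2$table$metric == "map"))
  expect_true(any(res2$table$metric == "pk_pk"))
})
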