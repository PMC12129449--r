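test_that("flat or degenerate envelopes yield no bursts, with a warning", {
  env <- makeEnvelope(rep(1, 5000), 1000)
  expect_warning(ev <- detectBursts(env), "degenerate")
  expect_equal(nrow(ev), 0L)
})

test_that("burst count at 150/min is recovered within 2%", {
  cfg <- simConfig(durationS = 60, burstRatePerMin = 150,
                   burstDurationMs = 100, seed = 21)
  sim <- simulateEmg(cfg)
  env <- signalEnvelope(sim$trace, 50, 50)
  ev <- detectBursts(env)
  nTrue <- nrow(truthBursts(sim$truth))
  expect_lt(abs(nrow(ev) / nTrue - 1), 0.02)
})

test_that("sub-refractory gaps are merged into one event", {
  rate <- 1000
  v <- rep(0.01, 2000)
  v[500:700] <- 1            # burst 1
  v[711:900] <- 1            # burst 2, 10 ms gap
  v <- v + 0.001 * sin(seq_len(2000))  # non-degenerate floor
  env <- makeEnvelope(abs(v), rate)
  ev <- detectBursts(env, detectionParams(minIntervalMs = 100,
                                          minBurstMs = 50,
                                          onsetRefineFrac = 0))
  expect_equal(nrow(ev), 1L)
  # a gap wider than the refractory interval stays two events
  ev2 <- detectBursts(env, detectionParams(minIntervalMs = 5,
                                           minBurstMs = 50,
                                           onsetRefineFrac = 0))
  expect_equal(nrow(ev2), 2L)
})

test_that("detected events are ordered, non-overlapping, and scale-free", {
  sim <- simulateEmg(simConfig(durationS = 30, seed = 13))
  env <- signalEnvelope(sim$trace, 50, 50)
  ev <- detectBursts(env)
  expect_true(all(diff(ev$onset_s) > 0))
  expect_true(all(ev$onset_s[-1] >= ev$offset_s[-nrow(ev)]))
  expect_true(all(ev$onset_s < ev$peak_time_s))
  expect_true(all(ev$peak_time_s <= ev$offset_s))
  # threshold is data-relative: rescaling changes nothing
  for (c in c(0.02, 5, 1e4)) {
    env2 <- makeEnvelope(samples(env) * c, samplingRate(env))
    expect_equal(nrow(detectBursts(env2)), nrow(ev))
  }
})

test_that("detection meets sensitivity/precision/onset targets on cohorts", {
  sens <- prec <- ons <- c()
  for (seed in c(31, 32, 33)) {
    sim <- simulateEmg(simConfig(durationS = 40, seed = seed))
    env <- signalEnvelope(sim$trace, 50, 50)
    m <- burstMetrics(env, detectBursts(env))
    r <- matchBursts(m, truthBursts(sim$truth))
    sens <- c(sens, r$sensitivity); prec <- c(prec, r$precision)
    ons <- c(ons, r$onsetErrS)
  }
  expect_gte(mean(sens), 0.95)
  expect_gte(mean(prec), 0.95)
  expect_lt(median(abs(ons)), 0.010)
})

test_that("breath detection recovers rate and deflections", {
  expect_equal(nrow(detectBreaths(SignalTrace(rep(0, 5000), 500))), 0L)
  cal <- plethCalibration(vkMl = 1, pkDefl = 0.5)
  sim <- simulatePleth(60, 500, breathRatePerMin = 100, trueVtMl = 2,
                       calib = cal, noiseSd = 0.003, seed = 17)
  br <- detectBreaths(sim$trace, detectionParams(minBurstMs = 40,
                                                 minIntervalMs = 150))
  tb <- truthBreaths(sim$truth)
  expect_lte(abs(nrow(br) - nrow(tb)), 2)
  expect_lt(abs(mean(br$deflection) / mean(tb$deflection) - 1), 0.02)
})

test_that("cardiac cycle detection recovers beats and pressures", {
  expect_equal(nrow(detectCardiacCycles(SignalTrace(rep(80, 3000), 500))), 0L)
  sim <- simulateArterialPressure(30, 1000, 400, 120, 90,
                                  noiseSd = 0, seed = 1)
  cy <- detectCardiacCycles(sim$trace)
  # n troughs delimit n-1 cycles; allow the half-open edge
  expect_lte(abs((nrow(cy) + 1) - nrow(truthBeats(sim$truth))), 1)
  expect_lt(max(abs(cy$sp - 120)), 0.05)
  expect_lt(max(abs(cy$dp - 90)), 0.05)
  simN <- simulateArterialPressure(30, 1000, 400, 120, 90,
                                   noiseSd = 1, seed = 4)
  cyN <- detectCardiacCycles(simN$trace)
  expect_lte(abs((nrow(cyN) + 1) - 200), 1)
})

test_that("preparation QC excludes exactly deteriorating preparations", {
  expect_identical(qcFlagPreparation(c(2.0, 2.4), 3.0), "include")
  expect_identical(qcFlagPreparation(c(2.0, 2.4), 2.1), "exclude")
  expect_identical(qcFlagPreparation(c(2.0), 2.0), "include")
  expect_error(qcFlagPreparation(numeric(), 1), "hypoxia")
  expect_error(qcFlagPreparation(c(1, 2), c(1, 2)), "maximal")
})
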