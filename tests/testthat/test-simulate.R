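test_that("identical configs give bit-identical traces and ground truth", {
  cfg <- simConfig(durationS = 3, seed = 7L)
  a <- simulateEmg(cfg)
  b <- simulateEmg(cfg)
  expect_identical(samples(a$trace), samples(b$trace))
  expect_identical(truthBursts(a$truth), truthBursts(b$truth))

  coh1 <- simulateCohort(3, simConfig(durationS = 2), cv = 0.3, seed = 5)
  coh2 <- simulateCohort(3, simConfig(durationS = 2), cv = 0.3, seed = 5)
  expect_identical(samples(coh1$subjects[[2]]$trace),
                   samples(coh2$subjects[[2]]$trace))
  expect_identical(coh1$metadata, coh2$metadata)
})

test_that("trace is zero outside burst support when tonic and noise vanish", {
  cfg <- simConfig(durationS = 2, burstRatePerMin = 30, tonicLevel = 0,
                   noiseFloor = 0, seed = 2)
  sim <- simulateEmg(cfg)
  tb <- truthBursts(sim$truth)
  expect_equal(nrow(tb), 1L)
  t <- traceTimes(sim$trace)
  pad <- 2 / samplingRate(sim$trace)
  outside <- t < tb$onset_s - pad | t > tb$offset_s + pad
  expect_true(all(samples(sim$trace)[outside] == 0))
  expect_gt(max(abs(samples(sim$trace)[!outside])), 0)
})

test_that("burst count at 150/min over 60 s is 150 within edge truncation", {
  cfg <- simConfig(durationS = 60, burstRatePerMin = 150,
                   burstDurationMs = 100, seed = 9)
  sim <- simulateEmg(cfg)
  expect_true(abs(nrow(truthBursts(sim$truth)) - 150) <= 1)
})

test_that("invalid simulation configs fail naming the offending field", {
  expect_error(simConfig(durationS = -1), "durationS")
  expect_error(simConfig(burstRatePerMin = 0), "burstRatePerMin")
  expect_error(simConfig(samplingRateHz = 1500, carrierBandHz = c(100, 1000)),
               "carrierBandHz")
  expect_error(simConfig(phasicAmplitude = -2), "phasicAmplitude")
})

test_that("integrating the noiseless envelope reproduces stored AUC to 0.1%", {
  cfg <- simConfig(durationS = 10, seed = 3,
                   intervention = interventionSpec(5, amplitudeGain = 2,
                                                   tonicGain = 1.8,
                                                   rampS = 2))
  sim <- simulateEmg(cfg)
  menv <- modulationEnvelope(cfg, sim$truth)
  v <- samples(menv); t <- traceTimes(menv); dt <- 1 / samplingRate(menv)
  tb <- truthBursts(sim$truth)
  for (i in seq_len(nrow(tb))) {
    idx <- which(t >= tb$onset_s[i] & t <= tb$offset_s[i])
    num <- (sum(v[idx]) - (v[idx[1]] + v[idx[length(idx)]]) / 2) * dt
    expect_lt(abs(num / tb$auc[i] - 1), 0.001)
  }
})

test_that("intervention scales true peaks by the amplitude gain", {
  iv <- interventionSpec(30, amplitudeGain = 2, tonicGain = 2, rampS = 5)
  cfg <- simConfig(durationS = 60, intervention = iv, seed = 4)
  sim <- simulateEmg(cfg)
  tb <- truthBursts(sim$truth)
  pre <- tb$peak_env[tb$onset_s < 30]
  post <- tb$peak_env[tb$onset_s > 36]  # past onset + ramp
  expect_lt(abs(mean(post) / mean(pre) - 2), 0.02)
  # effect persists to the end of the trace
  expect_lt(abs(tb$peak_env[nrow(tb)] / mean(pre) - 2), 0.02)
})

test_that("arterial simulator hits requested pressures and beat counts", {
  sim <- simulateArterialPressure(30, 1000, heartRateBpm = 400,
                                  sp = 120, dp = 90, noiseSd = 0, seed = 1)
  expect_equal(nrow(truthBeats(sim$truth)), 200L)
  x <- samples(sim$trace)
  expect_lt(abs(max(x) - 120), 0.01)
  expect_lt(abs(min(x) - 90), 0.01)
  # ground truth is independent of added noise
  simN <- simulateArterialPressure(30, 1000, 400, 120, 90,
                                   noiseSd = 3, seed = 99)
  expect_identical(truthBeats(simN$truth), truthBeats(sim$truth))
  expect_error(simulateArterialPressure(10, 1000, 400, sp = 90, dp = 120),
               "sp > dp")
})

test_that("pleth simulator is linear in tidal volume and flat at VT = 0", {
  cal <- plethCalibration(vkMl = 1, pkDefl = 0.5)
  flat <- simulatePleth(10, 500, 100, trueVtMl = 0, cal, seed = 1)
  expect_true(all(samples(flat$trace) == 0))
  a <- simulatePleth(10, 500, 100, 1.0, cal, seed = 1)
  b <- simulatePleth(10, 500, 100, 2.0, cal, seed = 1)
  expect_equal(max(samples(b$trace)), 2 * max(samples(a$trace)),
               tolerance = 1e-12)
  expect_equal(truthBreaths(b$truth)$deflection,
               2 * truthBreaths(a$truth)$deflection)
})

test_that("cohort variability follows the requested CV and gain contract", {
  base <- simConfig(durationS = 2)
  coh0 <- simulateCohort(4, base, cv = 0, seed = 11)
  expect_true(all(coh0$metadata$amp_mult == 1))
  cfgs <- lapply(coh0$subjects, `[[`, "config")
  expect_true(all(vapply(cfgs, function(cf)
    cf@phasicAmplitude == base@phasicAmplitude &&
      cf@burstRatePerMin == base@burstRatePerMin, logical(1))))

  iv <- interventionSpec(20, amplitudeGain = 2, tonicGain = 2, rampS = 0)
  coh <- simulateCohort(5, simConfig(durationS = 40, intervention = iv),
                        cv = 0, seed = 8)
  for (s in coh$subjects) {
    tb <- truthBursts(s$truth)
    ratio <- mean(tb$peak_env[tb$onset_s > 20]) /
      mean(tb$peak_env[tb$onset_s < 20])
    expect_lt(abs(ratio - 2), 0.02)
  }
})
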