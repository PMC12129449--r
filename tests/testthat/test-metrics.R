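test_that("burst metrics on hand-built envelopes are exact", {
  rate <- 1000
  # triangular burst: base 0.2 s, height 1, on a zero floor
  v <- rep(0, 2000)
  up <- seq(0, 1, length.out = 101)
  v[801:901] <- up; v[901:1001] <- rev(up)
  env <- makeEnvelope(v, rate)
  ev <- data.frame(onset_s = 0.8, offset_s = 1.0)
  m <- burstMetrics(env, ev, tonicWindowS = 0.2)
  expect_equal(m$auc, 0.1, tolerance = 1e-6)
  expect_equal(m$peak_amp, 1)
  expect_equal(m$tonic, 0)
  expect_equal(m$pk_pk, 1)

  # flat envelope: pk_pk = 0
  cst <- makeEnvelope(rep(0.7, 2000), rate)
  m2 <- burstMetrics(cst, ev, tonicWindowS = 0.2)
  expect_equal(m2$pk_pk, 0)
  expect_equal(m2$auc, 0.7 * 0.2, tolerance = 1e-6)
})

test_that("burst metrics scale equivariantly and recover simulated truth", {
  sim <- simulateEmg(simConfig(durationS = 30, seed = 41))
  env <- signalEnvelope(sim$trace, 50, 50)
  ev <- detectBursts(env)
  m1 <- burstMetrics(env, ev)
  c0 <- 3.7
  m2 <- burstMetrics(makeEnvelope(samples(env) * c0, samplingRate(env)), ev)
  for (col in c("peak_amp", "tonic", "pk_pk", "auc")) {
    expect_equal(m2[[col]], c0 * m1[[col]], tolerance = 1e-12)
  }
  r <- matchBursts(m1, truthBursts(sim$truth))
  expect_lt(abs(mean(r$pkErr)), 0.05)
  expect_lt(abs(mean(r$aucErr)), 0.05)
})

test_that("first burst falls back to the trailing tonic window, flagged", {
  sim <- simulateEmg(simConfig(durationS = 5, seed = 2))
  env <- signalEnvelope(sim$trace, 50, 50)
  m <- burstMetrics(env, detectBursts(env))
  expect_identical(m$tonic_source[1], "post")
  expect_true(all(m$tonic_source[-1] == "pre"))
})

test_that("event rate uses the median inter-onset interval", {
  expect_equal(eventRate(seq(0, 10, by = 0.4)), 150)
  expect_true(is.na(eventRate(3.2)))
  set.seed(1)
  on <- cumsum(0.5 + runif(100, -0.05, 0.05))
  expect_equal(eventRate(on), 60 / median(diff(on)))
  # window restriction
  expect_true(is.na(eventRate(c(1, 2, 3), windowS = c(10, 20))))
})

test_that("hemodynamics follow the MAP formula and rate definition", {
  cy <- data.frame(start_s = seq(0, 1.35, by = 0.15),
                   end_s = seq(0.15, 1.5, by = 0.15),
                   sp = 120, dp = 90)
  h <- hemodynamics(cy)
  expect_equal(h$map, 90 + (120 - 90) / 3)
  expect_equal(h$hr, 400)
  cy$sp <- cy$dp <- 100
  expect_equal(hemodynamics(cy)$map, 100)
  expect_true(is.na(hemodynamics(cy[1, ])$map))
  # dp <= map <= sp on random cycles
  set.seed(2)
  for (i in 1:20) {
    dp <- runif(1, 40, 100); sp <- dp + runif(1, 1, 80)
    cyr <- data.frame(start_s = c(0, 1), end_s = c(1, 2), sp = sp, dp = dp)
    h <- hemodynamics(cyr)
    expect_true(h$dp <= h$map && h$map <= h$sp)
  }
})

test_that("water vapor pressure matches steam-table references", {
  expect_equal(waterVaporPressure(298.15, 0), 0)
  expect_lt(abs(waterVaporPressure(298.15) - 23.76), 0.15)
  expect_lt(abs(waterVaporPressure(310.15) - 47.07), 0.20)
  expect_lt(abs(waterVaporPressure(293.15) - 17.54), 0.12)
  expect_error(waterVaporPressure(100), "range")
  expect_error(waterVaporPressure(300, 1.2), "rhFrac")
})

test_that("Drorbaugh-Fenn volume matches a hand-evaluated oracle", {
  expect_equal(drorbaughFennVt(0, plethCalibration()), 0)
  cal <- plethCalibration(vkMl = 1, pkDefl = 1, trK = 310.15, tcK = 298.15,
                          pbMmhg = 760, rhFrac = 0.5)
  # independent evaluation of the formula, written out here
  psat <- function(K) 6.1078 * 10^(7.5 * (K - 273.15) /
                                     ((K - 273.15) + 237.3)) * 0.750062
  pc <- 0.5 * psat(298.15); pr <- psat(310.15)
  num <- 310.15 * (760 - pc)
  oracle <- num / (num - 298.15 * (760 - pr))
  expect_equal(drorbaughFennVt(1, cal), oracle, tolerance = 1e-12)
  expect_lt(abs(oracle - 11.9), 0.1)

  # strictly increasing in deflection and in calibration volume
  expect_true(all(diff(drorbaughFennVt(seq(0, 2, 0.1), cal)) > 0))
  cal2 <- plethCalibration(vkMl = 2, pkDefl = 1, trK = 310.15,
                           tcK = 298.15, pbMmhg = 760, rhFrac = 0.5)
  expect_gt(drorbaughFennVt(1, cal2), drorbaughFennVt(1, cal))
  expect_error(drorbaughFennVt(-1, cal), "deflection")
})

test_that("degenerate plethysmograph physics are rejected by validity", {
  # chamber hotter than the body with a dry chamber drives the
  # denominator negative
  expect_error(plethCalibration(trK = 300, tcK = 372, rhFrac = 0,
                                pbMmhg = 760), "degenerate")
})

test_that("ventilation summary composes volume, weight and rate", {
  cal <- plethCalibration(vkMl = 1, pkDefl = 0.5, bodyMassKg = 0.4)
  pt <- 2 / drorbaughFennVt(1, cal)  # deflection encoding exactly 2 ml
  br <- data.frame(onset_s = seq(0, 59.4, by = 0.6),
                   offset_s = seq(0.24, 59.64, by = 0.6),
                   deflection = pt)
  vs <- ventilationSummary(br, cal)
  expect_equal(vs$vt_ml, 2, tolerance = 1e-9)
  expect_equal(vs$vt_ml_per_kg, 5, tolerance = 1e-9)
  expect_equal(vs$freq_per_min, 100)
  expect_equal(vs$ve_ml_per_kg_min, 500, tolerance = 1e-6)
  empty <- ventilationSummary(br, cal, windowS = c(100, 200))
  expect_true(is.na(empty$vt_ml))
  expect_equal(empty$n_breaths, 0L)
})

test_that("round trip from generated pleth trace recovers the volume", {
  cal <- plethCalibration(vkMl = 1, pkDefl = 0.5, bodyMassKg = 0.35)
  sim <- simulatePleth(30, 1000, 100, 2.0, cal, noiseSd = 0.003, seed = 5)
  br <- detectBreaths(sim$trace, detectionParams(minBurstMs = 40,
                                                 minIntervalMs = 150))
  vs <- ventilationSummary(br, cal)
  expect_lt(abs(vs$vt_ml / 2 - 1), 0.02)
  expect_lt(abs(vs$ve_ml_per_kg_min / (2 / 0.35 * 100) - 1), 0.03)
})
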