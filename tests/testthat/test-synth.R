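test_that("protocol arithmetic matches the scripted session", {
  p <- ProtocolSpec()
  expect_equal(breathingDuration(p), 1800)           # 6 x (240 + 60) = 30 min
  expect_equal(totalDuration(p), 2040)               # + 2 min pre/post
  expect_error(ProtocolSpec(normalDuration = -1), "durations")
  p1 <- ProtocolSpec(nWaves = 1)
  expect_equal(breathingDuration(p1), 300)
})

test_that("breathing waveform is silent when unmasked and scales as built", {
  pr <- ProtocolSpec()
  pars <- SimulationParams(seed = 11, rrJitter = 0, rrNormal = 20)
  sch <- breathSchedule(pr, pars)
  # pre and post segments: no breathing through the mask
  expect_equal(breathingWaveform(c(0, 60, 119.9), pr, pars, schedule = sch),
               c(0, 0, 0))
  expect_equal(breathingWaveform(c(1925, 2040), pr, pars, schedule = sch),
               c(0, 0))
  expect_error(breathingWaveform(2041, pr, pars), "span")
  # with jitter off, normal-phase period is exactly 60/rr = 3 s
  norm <- sch[sch$mode == "normal", ]
  expect_true(all(abs(norm$dt[norm$onset + norm$dt <
                                120 + 240 - 1e-9] - 3) < 1e-12))
  # peak-to-trough equals the configured amplitude times the zone gain
  t <- seq(130, 130 + 3, length.out = 2000)
  r1 <- breathingWaveform(t, pr, pars, zoneGain = 1, schedule = sch)
  expect_equal(max(r1) - min(r1), pars@ampNormal, tolerance = 1e-4)
  r3 <- breathingWaveform(t, pr, pars, zoneGain = 0.5, schedule = sch)
  expect_equal(max(r3) - min(r3), 0.5 * pars@ampNormal, tolerance = 1e-4)
  # deep-phase peak-to-trough is ampDeep/ampNormal times the normal one
  bd <- sch[sch$mode == "deep", ][2, ]   # one full deep breath
  td <- seq(bd$onset, bd$onset + bd$dt, length.out = 2000)
  rd <- breathingWaveform(td, pr, pars, zoneGain = 1, schedule = sch)
  expect_equal((max(rd) - min(rd)) / (max(r1) - min(r1)),
               pars@ampDeep / pars@ampNormal, tolerance = 1e-3)
})

test_that("waveform is zero-mean over each full breath", {
  pr <- ProtocolSpec()
  pars <- SimulationParams(seed = 12)
  sch <- breathSchedule(pr, pars)
  for (k in c(5L, 100L, 400L)) {
    tt <- seq(sch$onset[k], sch$onset[k] + sch$dt[k], length.out = 5000)
    tt <- tt[-length(tt)]
    r <- breathingWaveform(tt, pr, pars, schedule = sch)
    expect_lt(abs(mean(r)) / pars@ampNormal, 1e-3)
  }
})

test_that("breath schedule tiles each mode segment exactly", {
  pr <- ProtocolSpec()
  pars <- SimulationParams(seed = 13)
  sch <- breathSchedule(pr, pars)
  expect_equal(min(sch$onset), 120)
  expect_equal(max(sch$onset + sch$dt), 1920)
  # segment boundaries (every 240/60 s switch) coincide with breath edges
  bounds <- 120 + cumsum(rep(c(240, 60), 6))
  edges <- round(sch$onset + sch$dt, 9)
  expect_true(all(head(bounds, -1) %in% edges))
  # intervals stay within [0.5, 1.5] nominal periods
  per <- ifelse(sch$mode == "normal", 60 / pars@rrNormal, 60 / pars@rrDeep)
  expect_true(all(sch$dt > 0.45 * per & sch$dt < 1.6 * per))
})

test_that("noiseless simulation reproduces the exponential baseline exactly", {
  pars <- SimulationParams(seed = 1, noiseSigma = 0, ampNormal = 0,
                           ampDeep = 1e-9, artifactMagnitude = 0,
                           a = 9e5, b = 0.002, c = 1e5)
  rec <- simulateRecording(pars)
  tm <- samplingTimes(rec)
  ib <- tm >= 120 & tm < 1920
  expected <- 9e5 * exp(-0.002 * (tm[ib] - 120)) + 1e5
  expect_equal(unname(resistanceMatrix(rec)["L01", ib]), expected,
               tolerance = 1e-12)
  # value at donning time is a + c = 1e6
  expect_equal(unname(resistanceMatrix(rec)["L07", which(tm == 120)]), 1e6)
  # strict monotone decay towards c
  v <- resistanceMatrix(rec)["R03", ib]
  expect_true(all(diff(v) < 0))
  expect_gt(min(v), 1e5)
})

test_that("default recording has the 3 Hz sample count and overflow markers", {
  rec <- preprocessedSession(1)$rec  # clipped copy; also check raw
  raw <- simulateRecording(SimulationParams(seed = 1))
  expect_true(abs(ncol(raw) - 6120) <= 1)       # 2040 s x 3 Hz
  expect_equal(max(samplingTimes(raw)), 2040)
  tm <- samplingTimes(raw)
  pre <- resistanceMatrix(raw)[, tm < 119]
  expect_true(all(is.infinite(pre)))            # unmasked level overflows
  expect_true(all(resistanceMatrix(raw)[is.finite(resistanceMatrix(raw))] > 0))
})

test_that("simulation is bit-reproducible for a fixed seed", {
  r1 <- simulateRecording(SimulationParams(seed = 42))
  r2 <- simulateRecording(SimulationParams(seed = 42))
  expect_identical(resistanceMatrix(r1), resistanceMatrix(r2))
  expect_identical(breathLog(r1), breathLog(r2))
  r3 <- simulateRecording(SimulationParams(seed = 43))
  expect_false(identical(resistanceMatrix(r1), resistanceMatrix(r3)))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  x1 <- rnorm(3)
  set.seed(99)
  invisible(simulateRecording(SimulationParams(seed = 7)))
  x2 <- rnorm(3)
  expect_identical(x1, x2)
})

test_that("parameter validation rejects non-physical settings", {
  expect_error(SimulationParams(a = -1), "a, b, c")
  expect_error(SimulationParams(ampDeep = 100, ampNormal = 140), "ampDeep")
  expect_error(SimulationParams(rrNormal = 8, rrDeep = 18), "rrNormal")
  expect_error(SimulationParams(noiseSigma = NA_real_), "finite")
})

test_that("sensor layout carries 19 sensors per side with full zone cover", {
  lay <- defaultSensorLayout()
  expect_equal(nrow(lay@info), 38L)
  expect_equal(as.integer(table(lay@info$side)), c(19L, 19L))
  expect_setequal(unique(lay@info$zone),
                  c("mouth_nose", "top", "bottom", "side"))
  expect_true(all(lay@info$x >= 0 & lay@info$x <= 1))
  bad <- lay@info[-1, ]
  expect_error(SensorLayout(bad), "19 sensors")
})
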