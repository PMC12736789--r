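test_that("a clean sinusoid yields all intervals and full-swing amplitudes", {
  # 20 cycles/min, +-50 ohm, troughs at t = 1.5 + 3k: 20 troughs in 60 s
  t <- seq(0, 60, by = 0.1)
  x <- 1000 + 50 * cos(2 * pi * t / 3)
  ev <- detectBreaths(t, x, minPeriod = 2, baselineWindow = 9)
  expect_equal(nrow(ev), 19L)
  expect_equal(ev$dt, rep(3, 19), tolerance = 1e-9)
  expect_equal(ev$rr, rep(20, 19), tolerance = 1e-9)
  expect_equal(ev$amplitude, rep(100, 19), tolerance = 0.02)
})

test_that("flat or degenerate series produce no events", {
  t <- seq(0, 100, by = 1 / 3)
  expect_equal(nrow(detectBreaths(t, rep(5e5, length(t)))), 0L)
  expect_equal(nrow(detectBreaths(1:3, c(1, 2, 1))), 0L)
})

test_that("deep-phase intervals on simulated data match the generator log", {
  sess <- preprocessedSession(2)
  ev <- sessionEvents(sess)
  lg <- breathLog(sess$rec)
  # deep wave 3 spans [1260, 1320): compare detected troughs to the truth
  tr <- lg$trough_time[lg$wave == 3 & lg$mode == "deep"]
  det <- ev$t_start[ev$t_start >= min(tr) - 1 & ev$t_start <= max(tr) + 1]
  expect_equal(length(det), length(tr))
  expect_lt(max(abs(det - tr)), 0.7)  # within two samples at 3 Hz
  # mean deep interval near 60/8 = 7.5 s within jitter tolerance
  dd <- ev$dt[ev$t_start >= 1260 & ev$t_start + ev$dt <= 1320]
  expect_equal(mean(dd), 7.5, tolerance = 0.08)
})

test_that("anomaly screening merges split breaths and flags stray ones", {
  mk <- function(dts) {
    st <- cumsum(c(0, head(dts, -1)))
    data.frame(t_start = st, dt = dts, rr = 60 / dts, f = 1 / dts,
               amplitude = rep(80, length(dts)), anomaly = FALSE)
  }
  # spurious double peak splits one 6 s breath into 1 s + 5 s: merged
  ev <- screenAnomalies(mk(c(6, 1, 5, 6)))
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$dt, c(6, 6, 6))
  expect_false(any(ev$anomaly))
  # all comfortable 3 s breaths: untouched
  ev2 <- screenAnomalies(mk(rep(3, 5)))
  expect_false(any(ev2$anomaly))
  expect_equal(nrow(ev2), 5L)
  # unmergeable short interval (would exceed 15 s): flagged, not merged
  ev3 <- screenAnomalies(mk(c(8, 0.8, 14.9, 8)))
  expect_true(ev3$anomaly[2])
  expect_equal(nrow(ev3), 4L)
  # 0.8 s event at the flagging boundary
  ev4 <- screenAnomalies(mk(c(0.8)))
  expect_true(ev4$anomaly[1])
})

test_that("respiration metrics follow RR = 60/dt and f = 1/dt", {
  expect_equal(breathMetrics(3), list(rr = 20, f = 1 / 3))
  expect_equal(breathMetrics(7.5)$rr, 8)
  expect_equal(breathMetrics(60), list(rr = 1, f = 1 / 60))
  expect_error(breathMetrics(0), "positive")
  expect_error(breathMetrics(-2), "positive")
})

test_that("published per-wave means reproduce the printed session deltas", {
  tab <- read.csv(extdataPath("session_wave_rr.csv"), comment.char = "#")
  delta <- function(p, d) {
    g <- tab[tab$participant == p & tab$day == d, ]
    sessionFromWaveMeans(g$wave, g$normal_rr, g$deep_rr)@deltaRR
  }
  expect_equal(delta("P1", 2), 10.4, tolerance = 0.025)
  expect_equal(delta("P2", 1), 13.6, tolerance = 0.025)
  expect_equal(delta("P2", 3), 12.9, tolerance = 0.025)
  # missing wave (P2 day 2, wave 5): skipped, average over the other 4
  g <- tab[tab$participant == "P2" & tab$day == 2, ]
  s <- sessionFromWaveMeans(g$wave, g$normal_rr, g$deep_rr)
  expect_equal(s@wavesUsed, c(2L, 3L, 4L, 6L))
  expect_equal(s@deltaRR,
               mean(g$normal_rr[g$wave != 5] - g$deep_rr[g$wave != 5]))
  # single usable wave: delta is its plain difference
  s1 <- sessionFromWaveMeans(2, 20, 10)
  expect_equal(s1@deltaRR, 10)
})

test_that("wave summaries exclude wave 1 and straddling intervals", {
  sess <- preprocessedSession(4)
  ev <- sessionEvents(sess)
  ss <- summarizeWaves(ev, ProtocolSpec())
  expect_false(1L %in% ss@wavesUsed)
  expect_setequal(ss@wavesUsed, 2:6)
  # accepted intervals never span more than the wave plus one period
  w <- ss@waves
  dtsum <- vapply(2:6, function(i) {
    sel <- ev$t_start >= 120 + (i - 1) * 300 & ev$t_start < 120 + i * 300
    sum(ev$dt[sel])
  }, numeric(1))
  expect_true(all(dtsum <= 300 + 7.5 * 1.5))
})

test_that("simulated rates are recovered per wave and classified perfectly", {
  sess <- preprocessedSession(3)
  ev <- sessionEvents(sess)
  ss <- summarizeWaves(ev, ProtocolSpec())
  truth <- truthWaveMeans(breathLog(sess$rec))
  m <- merge(ss@waves, truth, by = c("wave", "mode"))
  expect_lt(max(abs(m$mean_rr - m$rr)), 0.5)
  w <- ss@waves[ss@waves$wave > 1, ]
  expect_lt(max(abs(w$mean_rr[w$mode == "deep"] - 8)), 0.5)
  expect_lt(max(abs(w$mean_rr[w$mode == "normal"] - 18)), 0.5)
  expect_identical(classifyBreathing(w$mean_rr), w$mode)
})

test_that("amplitude scales linearly with the simulated amplitude", {
  s1 <- preprocessedSession(6)
  s2 <- preprocessedSession(6, SimulationParams(seed = 6, ampNormal = 280,
                                                ampDeep = 960))
  a1 <- summarizeWaves(sessionEvents(s1), ProtocolSpec())@waves
  a2 <- summarizeWaves(sessionEvents(s2), ProtocolSpec())@waves
  r <- a2$mean_amplitude[a2$mode == "normal" & a2$wave > 1] /
    a1$mean_amplitude[a1$mode == "normal" & a1$wave > 1]
  expect_true(all(abs(r - 2) < 0.2))
})

test_that("breathing-mode threshold splits the published rate ranges", {
  expect_equal(classifyBreathing(18), "normal")
  expect_equal(classifyBreathing(8), "deep")
  expect_equal(classifyBreathing(15), "normal")  # tie goes to normal
  expect_equal(classifyBreathing(c(20, 5, 12)), c("normal", "deep", "deep"))
})
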