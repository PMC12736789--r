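test_that("overflow clipping saturates markers and large values at the limit", {
  expect_equal(clipOverflow(c(Inf, 5e8), 1e8), c(1e8, 1e8))
  expect_equal(clipOverflow(c(1e5, 2e5), 1e8), c(1e5, 2e5))
  expect_equal(clipOverflow(rep(Inf, 10), 1e8), rep(1e8, 10))
  # idempotent
  x <- c(1e5, Inf, 3e8, 5e7)
  expect_identical(clipOverflow(clipOverflow(x)), clipOverflow(x))
  # recording method clips the assay
  rec <- simulateRecording(SimulationParams(seed = 2))
  recC <- clipOverflow(rec)
  m <- resistanceMatrix(recC)
  expect_true(all(is.finite(m)) && max(m) <= 1e8)
})

test_that("motion-outlier removal flags exactly an injected spike", {
  # locally linear signal: replacement is the midpoint of the neighbours
  t <- seq(0, 100, by = 1 / 3)
  v <- 1000 - 2 * t
  i <- 150L
  vs <- v
  vs[i] <- 10 * vs[i]
  cl <- removeMotionOutliers(t, vs, window = 10, k = 5)
  expect_identical(which(cl@outlierMask), i)
  expect_equal(cl@values[i], mean(vs[c(i - 1L, i + 1L)]))
  expect_equal(cl@values[-i], vs[-i])
  expect_equal(cl@interpolatedCount, 1L)
})

test_that("spike on a simulated noiseless channel is flagged alone", {
  pars <- noiselessParams(3)
  rec <- clipOverflow(simulateRecording(pars))
  tm <- samplingTimes(rec)
  v <- resistanceMatrix(rec)["L02", ]
  ib <- which(tm > 200 & tm < 1900)
  i <- ib[1000]
  v[i] <- 10 * v[i]
  cl <- removeMotionOutliers(tm[ib], v[ib], window = 30, k = 5)
  expect_true(cl@outlierMask[1000])
  # brute-force: no other sample deviates 10-fold, so at most a couple of
  # samples near the spike may be touched and none elsewhere
  far <- abs(seq_along(ib) - 1000) > 2
  expect_equal(sum(cl@outlierMask[far]), 0L)
})

test_that("constant and short series behave as specified", {
  t <- seq(0, 50, by = 1 / 3)
  cl <- removeMotionOutliers(t, rep(7, length(t)))
  expect_equal(cl@interpolatedCount, 0L)
  expect_error(removeMotionOutliers(1:5, rnorm(5), window = 30), "shorter")
  # flagged sample between adjacent neighbours 100 and 200: midpoint 150
  v <- seq(-2900, 3100, by = 50)   # ramp passing through 100 and 200
  i <- which(v == 150)
  v[i] <- 5000
  tt <- seq_along(v)
  cl2 <- removeMotionOutliers(tt, v, window = 9, k = 5)
  expect_identical(which(cl2@outlierMask), i)
  expect_equal(cl2@values[i], 150)
})

test_that("noiseless artifact-free simulation yields almost no flags", {
  sessN <- preprocessedSession(5, noiselessParams(5))
  ib <- sessN$seg$labels == "breathing"
  frac <- mean(sessN$clean@outlierMask[ib])
  expect_lt(frac, 0.001)
})

test_that("phase segmentation follows the protocol clock", {
  pr <- ProtocolSpec()
  t <- c(60, 1000, 2000)
  seg <- segmentPhases(c(t, 2040), pr)
  expect_equal(seg$labels[1:3], c("pre", "breathing", "post"))
  expect_equal(seg$fitWindow, c(200, 1920))
  seg1 <- segmentPhases(seq(0, 2040, by = 1 / 3), ProtocolSpec(nWaves = 1))
  lab <- seg1$labels
  tt <- seq(0, 2040, by = 1 / 3)
  expect_true(all(lab[tt >= 120 & tt < 420] == "breathing"))
  expect_true(all(lab[tt >= 420 & tt <= 540] == "post"))
  expect_error(segmentPhases(seq(0, 1000), pr), "exceeds")
})

test_that("defective sensors are excluded with reasons, healthy ones kept", {
  sess <- preprocessedSession(1)
  expect_equal(nrow(sess$excl), 0L)  # all simulated channels healthy
  rec <- sess$rec
  m <- resistanceMatrix(rec)
  m["L05", ] <- 1234.5                       # frozen channel
  m["R08", ] <- 1e8                          # saturated for the whole run
  m["L11", 3000] <- -5                       # non-physical reading
  SummarizedExperiment::assay(rec, "resistance") <- m
  excl <- detectDefectiveSensors(rec)
  expect_setequal(excl$sensor_id, c("L05", "R08", "L11"))
  expect_equal(excl$reason[excl$sensor_id == "L05"], "flatline")
  expect_equal(excl$reason[excl$sensor_id == "R08"], "saturated")
  expect_equal(excl$reason[excl$sensor_id == "L11"], "nonpositive")
})

test_that("array mean is the per-timepoint mean over included channels", {
  lay <- defaultSensorLayout()
  n <- 10L
  m <- matrix(rep(c(100, 200, 300), n), nrow = 3)
  m <- rbind(m, matrix(150, nrow = 35, ncol = n))
  rownames(m) <- lay@info$sensor_id
  rec <- MaskRecording(m, time = seq_len(n), layout = lay)
  am3 <- arrayMean(rec, exclude = lay@info$sensor_id[-(1:3)])
  expect_equal(unique(am3@values), 200)
  am2 <- arrayMean(rec, exclude = lay@info$sensor_id[-(1:2)])
  expect_equal(unique(am2@values), 150)
  # two identical channels: mean equals either
  amAll <- arrayMean(rec, exclude = lay@info$sensor_id[1:3])
  expect_equal(unname(amAll@values), unname(m[4, ]))
  expect_error(arrayMean(rec, exclude = lay@info$sensor_id), "excluded")
})

test_that("array mean lies between the channel extremes", {
  sess <- preprocessedSession(1)
  m <- resistanceMatrix(sess$rec)
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  expect_true(all(sess$am@values >= lo - 1e-9 & sess$am@values <= hi + 1e-9))
})

test_that("change-point fallback recovers don/doff without metadata", {
  raw <- simulateRecording(SimulationParams(seed = 9))
  f <- withr::local_tempfile(fileext = ".csv")
  writeRecordingCSV(raw, f)
  # strip the protocol header comment so only the data remain
  lines <- readLines(f)
  writeLines(lines[!grepl("^# protocol", lines)], f)
  rec <- readRecordingCSV(f, layout = defaultSensorLayout())
  expect_null(protocol(rec))
  seg <- segmentPhases(rec)
  tm <- samplingTimes(rec)
  # don at 120 s, doff at 1920 s, located within a couple of samples
  expect_lt(abs(max(tm[seg$labels == "pre"]) - 120), 1)
  expect_lt(abs(max(tm[seg$labels == "breathing"]) - 1920), 1)
})
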