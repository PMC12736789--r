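test_that("min-max normalization maps window extrema to 0 and 1", {
  expect_equal(as.numeric(minmaxNormalize(c(100, 150, 200))), c(0, 0.5, 1))
  x <- rnorm(50)
  n <- minmaxNormalize(x)
  expect_equal(as.numeric(n[which.min(x)]), 0)
  expect_equal(as.numeric(n[which.max(x)]), 1)
  expect_error(minmaxNormalize(c(5, 5, 5)), "constant")
  # windowed variant restricts before normalizing
  t <- 1:10
  w <- minmaxNormalize(1:10 * 10, time = t, window = c(2.5, 7.5))
  expect_equal(as.numeric(w), (3:7 - 3) / 4, tolerance = 1e-12)
})

test_that("humidity index inverts the resistance scale", {
  expect_equal(as.numeric(humidityIndex(0)), 1)  # resistance minimum: wettest
  expect_equal(as.numeric(humidityIndex(1)), 0)
  expect_equal(as.numeric(humidityIndex(0.25)), 0.75)
  expect_error(humidityIndex(c(0.2, 1.4)), "normalized")
  # composed with normalization: monotone decreasing in raw resistance
  x <- sort(runif(30, 1e5, 1e6))
  idx <- humidityIndex(minmaxNormalize(x))
  expect_true(all(diff(as.numeric(idx)) < 0 + 1e-12))
})

test_that("breath-phase assignment tracks the flank sign convention", {
  # synthetic triangle breaths: falling flank = exhale, rising = inhale
  t <- seq(0, 30, by = 1 / 3)
  x <- 100 * (2 * abs((t / 5) %% 1 - 0.5))
  ph <- assignBreathPhase(t, x)
  mid <- which(t > 1 & t < 1.5)   # falling flank of the first cycle
  expect_true(all(ph[mid] == "exhale"))
  mid2 <- which(t > 3 & t < 4)    # rising flank
  expect_true(all(ph[mid2] == "inhale"))
})

test_that("phase labels agree with the generator on noiseless data", {
  pars <- noiselessParams(4)
  sess <- preprocessedSession(4, pars)
  tm <- sess$am@time
  ib <- which(tm > 200 & tm < 1900)
  det <- sess$am@values[ib] -
    maskflow:::.rollingMean(sess$am@values[ib], 91L)
  est <- assignBreathPhase(tm[ib], det)
  truth <- breathPhaseTruth(tm[ib], ProtocolSpec(), pars,
                            schedule = breathLog(sess$rec))
  expect_gt(mean(est == truth), 0.9)
})

test_that("frames stay in [0,1] and constant fields interpolate exactly", {
  sess <- preprocessedSession(1)
  fr <- makeFrames(sess$rec, times = seq(1500, 1520, by = 1), exclude = sess$excl)
  expect_true(all(fr@frameData$index >= 0 & fr@frameData$index <= 1))
  for (g in fr@grids) for (side in g) {
    v <- side[!is.na(side)]
    expect_true(all(v >= 0 & v <= 1))
  }
  # IDW of a constant is that constant, and fields respect the convex range
  px <- runif(50); py <- runif(50)
  f <- maskflow:::.idw(px, py, c(0.2, 0.5, 0.8), c(0.3, 0.6, 0.2),
                       c(0.4, 0.4, 0.4))
  expect_equal(f, rep(0.4, 50))
  f2 <- maskflow:::.idw(px, py, c(0.2, 0.5, 0.8), c(0.3, 0.6, 0.2),
                        c(0.1, 0.9, 0.5))
  expect_true(all(f2 >= 0.1 & f2 <= 0.9))
  # exact at a sensor location
  f3 <- maskflow:::.idw(0.2, 0.3, c(0.2, 0.5), c(0.3, 0.6), c(0.7, 0.1))
  expect_equal(f3, 0.7)
})

test_that("frame generation is deterministic and guards its inputs", {
  sess <- preprocessedSession(2)
  f1 <- makeFrames(sess$rec, times = c(1000, 1001))
  f2 <- makeFrames(sess$rec, times = c(1000, 1001))
  expect_identical(f1@frameData, f2@frameData)
  expect_identical(f1@grids, f2@grids)
  expect_error(makeFrames(sess$rec, times = 100), "outside")
  info <- sensorInfo(sess$rec)
  expect_error(makeFrames(sess$rec, times = 1000,
                          exclude = info$sensor_id[-(1:2)]), "3 usable")
})

test_that("zone means at deep exhale peaks follow the airflow ordering", {
  sess <- preprocessedSession(4)
  lg <- breathLog(sess$rec)
  troughs <- lg$trough_time[lg$mode == "deep" & lg$wave >= 2 &
                              lg$trough_time < 1900]
  fr <- makeFrames(sess$rec, times = troughs, exclude = sess$excl)
  zs <- zoneSummaries(fr)
  m <- setNames(zs$mean_index, zs$zone)
  expect_true(m[["mouth_nose"]] > m[["bottom"]])
  expect_true(m[["bottom"]] > m[["side"]])
  expect_true(m[["side"]] > m[["top"]])
  # late-session exhale peak: mouth zone close to maximal humidity
  parsN <- noiselessParams(4)
  sessN <- preprocessedSession(4, parsN)
  lgN <- breathLog(sessN$rec)
  lastTrough <- max(lgN$trough_time[lgN$trough_time < 1919])
  frN <- makeFrames(sessN$rec, times = lastTrough)
  zN <- zoneSummaries(frN)
  expect_gt(zN$mean_index[zN$zone == "mouth_nose"], 0.9)
})

test_that("zone summaries aggregate mean and range per zone", {
  fd <- data.frame(time = rep(c(1, 2), each = 2),
                   sensor_id = rep(c("a", "b"), 2),
                   side = "left", zone = rep(c("z1", "z2"), 2),
                   x = 0.5, y = 0.5,
                   index = c(0.2, 0.3, 0.6, 0.5),
                   phase = "exhale")
  fr <- new("SpatialFrameSet", frameData = fd, grids = list(),
            times = c(1, 2), phases = c("exhale", "exhale"),
            gridX = numeric(0), gridY = numeric(0))
  zs <- zoneSummaries(fr)
  expect_equal(zs$mean_index[zs$zone == "z1"], 0.4)
  expect_equal(zs$max_index[zs$zone == "z1"] - zs$min_index[zs$zone == "z1"],
               0.4)
  # single frame, single-sensor zone: mean equals that sensor's index
  zsOne <- zoneSummaries(fr, zones = "z2", phase = "exhale")
  expect_equal(zsOne$mean_index, mean(c(0.3, 0.5)))
  # empty zone carries the missing marker
  zMiss <- zoneSummaries(fr, zones = "z9")
  expect_true(is.na(zMiss$mean_index))
  expect_equal(zMiss$n_values, 0L)
})

test_that("3D shell coordinates sit on the ellipsoid surface", {
  lay <- defaultSensorLayout()@info
  left <- lay[lay$side == "left", ]
  xyz <- surfaceCoords(left$x, left$y, "left")
  r <- (xyz[, 1] / 0.6)^2 + (xyz[, 2] / 1.0)^2 + (xyz[, 3] / 0.8)^2
  expect_equal(unname(r), rep(1, nrow(left)), tolerance = 1e-9)
  xyzR <- surfaceCoords(left$x, left$y, "right")
  expect_equal(xyzR[, 2], -xyz[, 2])
})
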