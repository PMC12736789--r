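# Synthetic recording generator: exponential saturation baseline, scripted
# breathing oscillation, overflow saturation, don/doff motion artifacts.

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Per-sample protocol lookup: phase (pre/breathing/post), wave index and
# breathing mode (normal/deep) at each time. Vectorized; times outside
# [0, total] yield NA phase.
.protocolLookup <- function(protocol, t) {
  pre <- protocol@preDuration
  waveDur <- protocol@normalDuration + protocol@deepDuration
  bEnd <- pre + breathingDuration(protocol)
  total <- totalDuration(protocol)
  phase <- rep(NA_character_, length(t))
  phase[t >= 0 & t < pre] <- "pre"
  phase[t >= pre & t < bEnd] <- "breathing"
  phase[t >= bEnd & t <= total] <- "post"
  wave <- rep(NA_integer_, length(t))
  mode <- rep(NA_character_, length(t))
  ib <- which(phase == "breathing")
  if (length(ib)) {
    off <- t[ib] - pre
    wave[ib] <- pmin(as.integer(off %/% waveDur) + 1L, protocol@nWaves)
    inWave <- off - (wave[ib] - 1L) * waveDur
    mode[ib] <- ifelse(inWave < protocol@normalDuration, "normal", "deep")
  }
  data.frame(phase = phase, wave = wave, mode = mode)
}

#' Draw the breath schedule for a simulated session
#'
#' Draws breath onset times over the breathing segment of the protocol.
#' Inter-breath intervals are lognormal with mean 60/rate (rate =
#' \code{rrNormal} or \code{rrDeep} by instructed mode) and fractional s.d.
#' \code{rrJitter}. Breaths are phase-aligned: a new breath starts at every
#' normal/deep mode boundary (the participant switches on cue), so the last
#' interval of each segment is truncated -- or, if less than half a nominal
#' period would remain, the previous breath is extended -- to end exactly at
#' the boundary. Consumes the RNG stream (callers wanting reproducibility
#' should seed, as \code{\link{simulateRecording}} does).
#'
#' @param protocol a \code{\link{ProtocolSpec}}.
#' @param params a \code{\link{SimulationParams}}.
#' @return data.frame(onset, dt, mode, wave, trough_time): one row per
#'   breath; \code{trough_time} is where the resistance minimum (end of
#'   exhale) falls within the breath.
#' @export
breathSchedule <- function(protocol, params) {
  validObject(protocol); validObject(params)
  cv <- params@rrJitter
  sdlog <- sqrt(log(1 + cv^2))
  pre <- protocol@preDuration
  waveDur <- protocol@normalDuration + protocol@deepDuration
  out <- vector("list", 2L * protocol@nWaves)
  k <- 0L
  for (w in seq_len(protocol@nWaves)) {
    segStart <- pre + (w - 1L) * waveDur
    for (mode in c("normal", "deep")) {
      dur <- if (mode == "normal") protocol@normalDuration else protocol@deepDuration
      rate <- if (mode == "normal") params@rrNormal else params@rrDeep
      s0 <- segStart + if (mode == "deep") protocol@normalDuration else 0
      period <- 60 / rate
      meanlog <- log(period) - sdlog^2 / 2
      onsets <- numeric(0); dts <- numeric(0)
      t <- 0
      while (t < dur) {
        dt <- if (cv > 0) stats::rlnorm(1L, meanlog, sdlog) else period
        onsets <- c(onsets, t); dts <- c(dts, dt)
        t <- t + dt
      }
      # align the segment end with a breath boundary
      n <- length(onsets)
      remain <- dur - onsets[n]
      if (remain >= 0.5 * period || n == 1L) {
        dts[n] <- remain
      } else {
        onsets <- onsets[-n]; dts <- dts[-n]
        n <- n - 1L
        dts[n] <- dur - onsets[n]
      }
      k <- k + 1L
      out[[k]] <- data.frame(onset = s0 + onsets, dt = dts,
                             mode = mode, wave = w)
    }
  }
  sched <- do.call(rbind, out)
  sched$trough_time <- sched$onset + params@exhaleFraction * sched$dt
  rownames(sched) <- NULL
  sched
}

# Within-breath pulse: u in [0,1) -> w in [0,1], a raised cosine whose peak
# sits at exhaleFraction (asymmetric: fast exhale fall of resistance, slower
# inhale recovery). Mean and median of w over a full breath are exactly 1/2,
# so amp * (1/2 - w) is a zero-mean oscillation with peak-to-trough amp.
.breathPulse <- function(u, exhaleFraction) {
  g <- ifelse(u <= exhaleFraction,
              u / (2 * exhaleFraction),
              0.5 + (u - exhaleFraction) / (2 * (1 - exhaleFraction)))
  (1 - cos(2 * pi * g)) / 2
}

#' Breathing oscillation term
#'
#' The additive breathing component r(t) of a simulated resistance series:
#' zero during the unmasked pre/post segments; during breathing, a zero-mean
#' asymmetric raised-cosine pulse per breath whose peak-to-trough amplitude
#' is \code{ampNormal} (normal waves) or \code{ampDeep} (deep waves) times
#' \code{zoneGain}. Resistance falls during exhale (humidity up, resistance
#' down: the sensing film responds inversely to humidity).
#'
#' @param t time(s) in seconds from recording start; must lie within
#'   [0, totalDuration(protocol)].
#' @param protocol a \code{\link{ProtocolSpec}}.
#' @param params a \code{\link{SimulationParams}}.
#' @param zoneGain dimensionless amplitude multiplier for the sensor's zone.
#' @param schedule optional precomputed \code{\link{breathSchedule}}; when
#'   NULL one is drawn deterministically from \code{params@seed}.
#' @return numeric vector of resistance offsets in ohms.
#' @export
breathingWaveform <- function(t, protocol, params, zoneGain = 1,
                              schedule = NULL) {
  total <- totalDuration(protocol)
  if (any(t < 0 | t > total))
    stop("t outside the recording span [0, ", total, "]")
  if (is.null(schedule))
    schedule <- .withSeed(params@seed, breathSchedule(protocol, params))
  r <- numeric(length(t))
  lk <- .protocolLookup(protocol, t)
  ib <- which(lk$phase == "breathing")
  if (!length(ib)) return(r)
  idx <- findInterval(t[ib], schedule$onset)
  idx[idx < 1L] <- 1L
  u <- (t[ib] - schedule$onset[idx]) / schedule$dt[idx]
  u <- pmin(pmax(u, 0), 1)
  amp <- ifelse(schedule$mode[idx] == "normal", params@ampNormal,
                params@ampDeep)
  r[ib] <- amp * zoneGain * (0.5 - .breathPulse(u, params@exhaleFraction))
  r
}

#' True within-breath phase labels for a simulated schedule
#'
#' Ground-truth inhale/exhale labels from the generator: "exhale" while the
#' simulated resistance is on its falling flank (the first
#' \code{exhaleFraction} of each breath), "inhale" on the recovery flank,
#' "none" outside the breathing segment.
#'
#' @inheritParams breathingWaveform
#' @return character vector of labels, one per element of \code{t}.
#' @export
breathPhaseTruth <- function(t, protocol, params, schedule = NULL) {
  if (is.null(schedule))
    schedule <- .withSeed(params@seed, breathSchedule(protocol, params))
  lab <- rep("none", length(t))
  lk <- .protocolLookup(protocol, t)
  ib <- which(lk$phase == "breathing")
  if (!length(ib)) return(lab)
  idx <- findInterval(t[ib], schedule$onset)
  idx[idx < 1L] <- 1L
  u <- (t[ib] - schedule$onset[idx]) / schedule$dt[idx]
  lab[ib] <- ifelse(u <= params@exhaleFraction, "exhale", "inhale")
  lab
}

#' Simulate a sensor-array recording
#'
#' Generates a full scripted session at a nominal 3 Hz multiplexed sampling
#' rate. During mask wear each sensor follows the saturation baseline
#' \code{a * exp(-b * (t - t_don)) + c} plus its zone-scaled breathing
#' oscillation and Gaussian noise; during the unmasked pre/post segments the
#' dry-sensor level applies (readings above \code{overflowLimit} are stored
#' as \code{Inf} overflow markers, the way a range-limited logger reports
#' them). Two-sided multiplicative spike artifacts are injected for
#' \code{artifactDuration} seconds after the don and doff events. The result
#' is bit-reproducible for a given \code{params@seed}.
#'
#' @param params a \code{\link{SimulationParams}}.
#' @param protocol a \code{\link{ProtocolSpec}}.
#' @param layout a \code{\link{SensorLayout}}; zones missing from
#'   \code{params@zoneGains} get gain 0.
#' @param sampleRate samples per second per channel.
#' @param ambientTemp,ambientRH ambient metadata recorded with the session.
#' @return a \code{\link{MaskRecording}} carrying the generator's breath
#'   truth log and parameters in its metadata.
#' @examples
#' rec <- simulateRecording(SimulationParams(seed = 7))
#' dim(resistanceMatrix(rec))  # 38 sensors x 6121 samples
#' @export
simulateRecording <- function(params = SimulationParams(),
                              protocol = ProtocolSpec(),
                              layout = defaultSensorLayout(),
                              sampleRate = 3,
                              ambientTemp = 22.8, ambientRH = 53.0) {
  validObject(params); validObject(protocol); validObject(layout)
  total <- totalDuration(protocol)
  n <- as.integer(floor(total * sampleRate)) + 1L
  time <- (seq_len(n) - 1L) / sampleRate
  info <- layout@info
  gains <- params@zoneGains[info$zone]
  gains[is.na(gains)] <- 0

  lk <- .protocolLookup(protocol, time)
  breathing <- lk$phase == "breathing"
  tDon <- protocol@preDuration
  tDoff <- protocol@preDuration + breathingDuration(protocol)

  .withSeed(params@seed, {
    schedule <- breathSchedule(protocol, params)
    base <- ifelse(breathing,
                   params@a * exp(-params@b * (time - tDon)) + params@c,
                   params@unmaskedLevel)
    pulse <- breathingWaveform(time, protocol, params, zoneGain = 1,
                               schedule = schedule)
    mat <- matrix(0, nrow = nrow(info), ncol = n,
                  dimnames = list(info$sensor_id, NULL))
    for (s in seq_len(nrow(info))) {
      v <- base + gains[s] * pulse
      if (params@noiseSigma > 0)
        v <- v + rnorm(n, 0, params@noiseSigma)
      mat[s, ] <- v
    }
    # don/doff motion artifacts: alternating multiplicative two-sided spikes
    if (params@artifactMagnitude > 0 && params@artifactDuration > 0) {
      for (tEv in c(tDon, tDoff)) {
        iEv <- which(time >= tEv & time < tEv + params@artifactDuration)
        if (!length(iEv)) next
        fac <- ifelse(seq_along(iEv) %% 2L == 1L,
                      1 + params@artifactMagnitude,
                      1 / (1 + params@artifactMagnitude))
        mat[, iEv] <- sweep(mat[, iEv, drop = FALSE], 2L, fac, `*`)
      }
    }
    mat[mat > params@overflowLimit] <- Inf
    mat[is.finite(mat) & mat <= 0] <- .Machine$double.eps
    MaskRecording(mat, time, layout,
                  ambientTemp = ambientTemp, ambientRH = ambientRH,
                  protocol = protocol, breathLog = schedule, params = params)
  })
}

#' Write a recording to the data-logger CSV dialect
#'
#' Header comment lines carry the ambient metadata and protocol; the table
#' has a \code{time_s} column plus one column per sensor id. Overflow
#' markers are written as the literal token \code{overflow}. Finite values
#' are written with 17 significant digits so that a write/read cycle is
#' bit-exact.
#'
#' @param rec a \code{\link{MaskRecording}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readRecordingCSV}}
#' @export
writeRecordingCSV <- function(rec, path) {
  stopifnot(is(rec, "MaskRecording"))
  if (ncol(rec) == 0L || nrow(rec) == 0L)
    stop("cannot write an empty recording")
  mat <- resistanceMatrix(rec)
  amb <- ambientConditions(rec)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# ambient_temp_c=%s", format(amb[["temp_c"]])), con)
  writeLines(sprintf("# ambient_rh_pct=%s", format(amb[["rh_pct"]])), con)
  pr <- protocol(rec)
  if (!is.null(pr))
    writeLines(sprintf(
      "# protocol=%s",
      jsonlite::toJSON(list(preDuration = pr@preDuration, nWaves = pr@nWaves,
                            normalDuration = pr@normalDuration,
                            deepDuration = pr@deepDuration,
                            postDuration = pr@postDuration),
                       auto_unbox = TRUE)), con)
  fmtNum <- function(v) {
    out <- sprintf("%.17g", v)
    out[!is.finite(v)] <- "overflow"
    out
  }
  writeLines(paste(c("time_s", rownames(mat)), collapse = ","), con)
  body <- matrix(c(sprintf("%.17g", samplingTimes(rec)),
                   fmtNum(t(mat))),
                 nrow = ncol(mat))
  writeLines(apply(body, 1L, paste, collapse = ","), con)
  invisible(path)
}
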