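# Breath-by-breath feature extraction: peak detection on the negated
# detrended resistance (exhale = resistance trough), inter-breath intervals,
# anomaly screening, per-wave summaries and normal/deep classification.

# Local maxima with prominence and minimum-distance filtering.
# Prominence of a peak: its height above the higher of the two valley bases
# found by walking outward until a strictly higher sample (or the series
# edge) is met. Higher peaks win ties when enforcing min distance.
.findPeaks <- function(x, minDistance = 1L, prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    j <- i
    leftMin <- x[i]
    while (j > 1L && x[j - 1L] <= x[i]) {
      j <- j - 1L
      if (x[j] < leftMin) leftMin <- x[j]
    }
    j <- i
    rightMin <- x[i]
    while (j < n && x[j + 1L] <= x[i]) {
      j <- j + 1L
      if (x[j] < rightMin) rightMin <- x[j]
    }
    x[i] - max(leftMin, rightMin)
  }, numeric(1))
  thr <- if (length(prominence) == 1L) rep(prominence, length(cand))
         else prominence[cand]
  keep <- cand[prom >= thr & prom > 0]
  if (length(keep) < 2L || minDistance <= 1L) return(keep)
  ord <- keep[order(x[keep], decreasing = TRUE)]
  taken <- integer(0)
  for (i in ord)
    if (!length(taken) || all(abs(taken - i) >= minDistance))
      taken <- c(taken, i)
  sort(taken)
}

# rolling inter-quartile range (centered window, edge-extended)
.rollingIQR <- function(x, width) {
  n <- length(x)
  width <- min(width, n)
  half <- width %/% 2L
  starts <- pmax(1L, seq_len(n) - half)
  ends <- pmin(n, seq_len(n) + half)
  # evaluate on a thinned grid and interpolate: the IQR varies slowly
  grid <- unique(c(seq(1L, n, by = max(1L, half %/% 2L)), n))
  vals <- vapply(grid, function(i)
    IQR(x[starts[i]:ends[i]], type = 7), numeric(1))
  approx(grid, vals, xout = seq_len(n), rule = 2)$y
}

#' Detect individual breaths in a resistance series
#'
#' The series is detrended by subtracting a rolling-mean baseline (window
#' covering several breath periods, which averages the zero-mean breathing
#' oscillation away), negated so that exhale resistance
#' troughs become peaks, and scanned for local maxima with a minimum
#' spacing of \code{minPeriod} seconds and a prominence threshold. Each pair
#' of consecutive peaks yields one \code{BreathEvent}-shaped row: the
#' inter-breath interval dt, respiration rate RR = 60/dt, frequency
#' f = 1/dt, and the amplitude A = Rmax - Rmin of the detrended signal
#' between the two peaks.
#'
#' @param time sample times, seconds (or a \code{\link{CleanSeries}}, in
#'   which case \code{values} is ignored).
#' @param values resistance values, ohms.
#' @param minPeriod minimum credible breath period, seconds (default 2 s,
#'   i.e. at most 30 breaths/min).
#' @param prominence peak prominence threshold in ohms; default 0.2 times a
#'   rolling inter-quartile range of the detrended signal.
#' @param baselineWindow detrending window, seconds (default 30 s, at least
#'   three breath periods).
#' @return data.frame(t_start, dt, rr, f, amplitude, anomaly): one row per
#'   complete inter-breath interval, ordered in time; zero rows for flat or
#'   too-short series.
#' @export
detectBreaths <- function(time, values = NULL, minPeriod = 2,
                          prominence = NULL, baselineWindow = 30) {
  if (is(time, "CleanSeries")) {
    values <- time@values
    time <- time@time
  }
  if (is(time, "ArrayMeanSeries")) {
    values <- time@values
    time <- time@time
  }
  empty <- data.frame(t_start = numeric(0), dt = numeric(0),
                      rr = numeric(0), f = numeric(0),
                      amplitude = numeric(0), anomaly = logical(0))
  if (length(time) < 5L || sd(values) == 0) return(empty)
  fs <- 1 / median(diff(time))
  base <- .rollingMean(values, .oddWindow(baselineWindow, fs))
  det <- values - base
  y <- -det
  if (is.null(prominence))
    prominence <- 0.2 * .rollingIQR(det, .oddWindow(3 * baselineWindow, fs))
  peaks <- .findPeaks(y, minDistance = max(1L, as.integer(round(minPeriod * fs))),
                      prominence = prominence)
  if (length(peaks) < 2L) return(empty)
  m <- length(peaks) - 1L
  amp <- vapply(seq_len(m), function(i) {
    seg <- det[peaks[i]:peaks[i + 1L]]
    max(seg) - min(seg)
  }, numeric(1))
  dt <- diff(time[peaks])
  data.frame(t_start = time[peaks[-length(peaks)]], dt = dt,
             rr = 60 / dt, f = 1 / dt, amplitude = amp,
             anomaly = FALSE)
}

#' Screen anomalous (too short) breaths
#'
#' Inter-breath intervals at or below \code{minDt} are spurious (typically a
#' double-detected peak splitting one breath). Each such interval is
#' re-examined against its successor: if merging the two yields an interval
#' within [\code{minDt}, \code{maxMergedDt}], they are merged into a single
#' breath (amplitude = the larger of the two); otherwise the event is
#' flagged and later excluded from wave aggregates.
#'
#' @param events data.frame from \code{\link{detectBreaths}}.
#' @param minDt anomaly threshold, seconds (default 1 s).
#' @param maxMergedDt longest physiologically credible merged interval,
#'   seconds.
#' @return the events data.frame with merges applied and \code{anomaly} set.
#' @export
screenAnomalies <- function(events, minDt = 1, maxMergedDt = 15) {
  stopifnot(minDt > 0)
  i <- 1L
  while (i <= nrow(events)) {
    if (events$dt[i] <= minDt) {
      if (i < nrow(events)) {
        merged <- events$dt[i] + events$dt[i + 1L]
        if (merged >= minDt && merged <= maxMergedDt) {
          events$dt[i] <- merged
          events$rr[i] <- 60 / merged
          events$f[i] <- 1 / merged
          events$amplitude[i] <- max(events$amplitude[i],
                                     events$amplitude[i + 1L])
          events <- events[-(i + 1L), , drop = FALSE]
          next
        }
      }
      events$anomaly[i] <- TRUE
    }
    i <- i + 1L
  }
  rownames(events) <- NULL
  events
}

#' Respiration rate and frequency from an inter-breath interval
#'
#' @param dt inter-breath interval(s), seconds, > 0.
#' @return list(rr = 60/dt in breaths/min, f = 1/dt in Hz).
#' @examples
#' breathMetrics(3)    # 20 bpm
#' breathMetrics(7.5)  # 8 bpm
#' @export
breathMetrics <- function(dt) {
  if (any(!is.finite(dt)) || any(dt <= 0))
    stop("dt must be positive and finite")
  list(rr = 60 / dt, f = 1 / dt)
}

#' Summarize breaths per wave and breathing mode
#'
#' Assigns each unflagged breath to a protocol wave and mode by the phase
#' containing its starting peak, then averages RR and amplitude per
#' wave x mode. Intervals whose span crosses a normal/deep (or
#' breathing/post) boundary are measured between breaths of two different
#' instructed modes and are dropped from the averages. The session-level
#' differences (mean normal RR minus mean deep RR, and the amplitude
#' analogue) are averaged over waves 2..n in which both modes are available;
#' wave 1 is always excluded because the membrane is still saturating.
#'
#' @param events breath events (after \code{\link{screenAnomalies}}).
#' @param protocol a \code{\link{ProtocolSpec}}.
#' @param dropStraddling drop mode-boundary-crossing intervals (default
#'   TRUE).
#' @return a \code{\link{SessionSummary}}.
#' @export
summarizeWaves <- function(events, protocol, dropStraddling = TRUE) {
  lkStart <- .protocolLookup(protocol, events$t_start)
  keep <- !events$anomaly & lkStart$phase == "breathing"
  if (dropStraddling) {
    lkEnd <- .protocolLookup(protocol, pmin(events$t_start + events$dt,
                                            totalDuration(protocol)))
    same <- lkStart$phase == lkEnd$phase &
      !is.na(lkStart$mode) & !is.na(lkEnd$mode) &
      lkStart$mode == lkEnd$mode & lkStart$wave == lkEnd$wave
    keep <- keep & same
  }
  ev <- events[keep, , drop = FALSE]
  lk <- lkStart[keep, , drop = FALSE]
  grid <- expand.grid(wave = seq_len(protocol@nWaves),
                      mode = c("normal", "deep"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- lk$wave == grid$wave[i] & lk$mode == grid$mode[i]
    n <- sum(sel)
    data.frame(wave = grid$wave[i], mode = grid$mode[i],
               mean_rr = if (n) mean(ev$rr[sel]) else NA_real_,
               mean_amplitude = if (n) mean(ev$amplitude[sel]) else NA_real_,
               n_breaths = n, available = n > 0L)
  })
  waves <- do.call(rbind, rows)
  waves <- waves[order(waves$wave, waves$mode, decreasing = c(FALSE, TRUE),
                       method = "radix"), ]
  rownames(waves) <- NULL
  .sessionFromWaveTable(waves)
}

# session-level deltas from the per-wave table (wave 1 excluded; waves with
# either mode missing skipped)
.sessionFromWaveTable <- function(waves) {
  wn <- waves[waves$mode == "normal", ]
  wd <- waves[waves$mode == "deep", ]
  wd <- wd[match(wn$wave, wd$wave), ]
  ok <- wn$wave > 1L & wn$available & wd$available &
    is.finite(wn$mean_rr) & is.finite(wd$mean_rr)
  if (!any(ok))
    stop("no usable waves: need at least one wave past wave 1 with both modes")
  deltaRR <- mean(wn$mean_rr[ok] - wd$mean_rr[ok])
  ampOk <- ok & is.finite(wn$mean_amplitude) & is.finite(wd$mean_amplitude)
  deltaAmp <- if (any(ampOk))
    mean(abs(wd$mean_amplitude[ampOk] - wn$mean_amplitude[ampOk]))
  else NA_real_
  new("SessionSummary", waves = waves, deltaRR = deltaRR,
      deltaAmp = deltaAmp, wavesUsed = as.integer(wn$wave[ok]))
}

#' Build a session summary from per-wave means
#'
#' Entry point for pre-aggregated per-wave mean respiration rates (e.g. a
#' published session table): computes the session-level mean RR and
#' amplitude differences under the same rules as
#' \code{\link{summarizeWaves}} (wave 1 excluded, waves with a missing mode
#' skipped). Use \code{NA} for unavailable wave/mode cells.
#'
#' @param wave wave indices.
#' @param normalRR,deepRR per-wave mean RR (breaths/min) for the two modes.
#' @param normalAmp,deepAmp optional per-wave mean amplitudes (ohms).
#' @return a \code{\link{SessionSummary}}.
#' @examples
#' s <- sessionFromWaveMeans(2:6,
#'        normalRR = c(18.6, 18.4, 19.1, 18.6, 18.1),
#'        deepRR   = c(7.5, 8.8, 8.7, 7.9, 7.9))
#' s@deltaRR  # 10.4 bpm
#' @export
sessionFromWaveMeans <- function(wave, normalRR, deepRR,
                                 normalAmp = NULL, deepAmp = NULL) {
  stopifnot(length(wave) == length(normalRR),
            length(wave) == length(deepRR))
  if (is.null(normalAmp)) normalAmp <- rep(NA_real_, length(wave))
  if (is.null(deepAmp)) deepAmp <- rep(NA_real_, length(wave))
  waves <- rbind(
    data.frame(wave = wave, mode = "normal", mean_rr = normalRR,
               mean_amplitude = normalAmp,
               n_breaths = NA_integer_, available = is.finite(normalRR)),
    data.frame(wave = wave, mode = "deep", mean_rr = deepRR,
               mean_amplitude = deepAmp,
               n_breaths = NA_integer_, available = is.finite(deepRR)))
  waves <- waves[order(waves$wave), ]
  rownames(waves) <- NULL
  .sessionFromWaveTable(waves)
}

#' Classify breathing mode from a mean respiration rate
#'
#' Deep breathing is slower: a window or wave whose mean RR falls below
#' \code{rrThreshold} is labelled deep, otherwise normal (ties -> normal).
#' The default threshold of 15 breaths/min sits between typical instructed
#' deep rates (roughly 5--14 bpm) and the 12--20 bpm medical-standard
#' normal range.
#'
#' @param meanRR mean respiration rate(s), breaths/min.
#' @param rrThreshold decision threshold, breaths/min.
#' @return character vector "normal"/"deep".
#' @export
classifyBreathing <- function(meanRR, rrThreshold = 15) {
  ifelse(meanRR < rrThreshold, "deep", "normal")
}
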