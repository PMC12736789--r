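# Preprocessing: overflow clipping, robust motion-outlier removal, protocol
# phase segmentation, defective-sensor exclusion, array mean.

#' @rdname clipOverflow
#' @export
setMethod("clipOverflow", "numeric", function(x, limit = 1e8) {
  stopifnot(length(limit) == 1L, is.finite(limit), limit > 0)
  x[is.infinite(x) | x > limit] <- limit
  x
})

#' @rdname clipOverflow
#' @export
setMethod("clipOverflow", "MaskRecording", function(x, limit = 1e8) {
  m <- resistanceMatrix(x)
  m[is.infinite(m) | m > limit] <- limit
  SummarizedExperiment::assay(x, "resistance") <- m
  x
})

# odd window length in samples for a duration in seconds
.oddWindow <- function(seconds, fs, minSamples = 3L) {
  w <- max(minSamples, as.integer(round(seconds * fs)))
  if (w %% 2L == 0L) w + 1L else w
}

# centered rolling mean with shrinking (partial) windows at the edges;
# unlike a rolling median it does not collapse onto the signal when the
# series is locally monotone, so it averages a zero-mean oscillation away
# and estimates the slow baseline
.rollingMean <- function(x, w) {
  n <- length(x)
  half <- min(w %/% 2L, n - 1L)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Remove motion outliers from a resistance series
#'
#' Flags samples deviating from a rolling median by more than \code{k} times
#' a rolling MAD scale (floored by the median absolute sample-to-sample
#' step, so trend- and breathing-driven excursions are never spike
#' candidates) and replaces them by linear interpolation between the nearest
#' unflagged neighbours (nearest-value fill at the ends). The rolling median
#' is robust to the short (a few samples) don/doff spike artifacts this
#' step targets.
#'
#' When phase labels are supplied each contiguous phase segment is cleaned
#' independently, so the don/doff level steps between unmasked and breathing
#' segments neither trigger flags nor leak into the interpolation.
#'
#' @param time sample times, seconds.
#' @param values resistance, ohms (finite; clip overflow first).
#' @param window rolling window length, seconds (default 30 s: several
#'   breath periods even for slow deep breathing, yet short against the
#'   ~500 s saturation timescale; must cover at least 3 samples).
#' @param k flagging threshold in rolling-MAD units (default 5).
#' @param labels optional per-sample phase labels (from
#'   \code{\link{segmentPhases}}); segments are cleaned independently.
#' @return a \code{\link{CleanSeries}}.
#' @export
removeMotionOutliers <- function(time, values, window = 30, k = 5,
                                 labels = NULL) {
  stopifnot(length(time) == length(values), k > 0)
  if (any(!is.finite(values)))
    stop("values must be finite; apply clipOverflow() first")
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(values))
    runs <- rle(labels)
    ends <- cumsum(runs$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    flag <- logical(length(values))
    clean <- values
    for (r in seq_along(starts)) {
      i <- starts[r]:ends[r]
      cs <- removeMotionOutliers(time[i], values[i], window = window, k = k)
      flag[i] <- cs@outlierMask
      clean[i] <- cs@values
    }
    return(new("CleanSeries", time = time, values = clean,
               outlierMask = flag, interpolatedCount = as.integer(sum(flag)),
               phaseLabels = as.character(labels)))
  }
  fs <- 1 / median(diff(time))
  w <- .oddWindow(window, fs)
  if (length(values) < w)
    stop("series shorter than the rolling window")
  # Hampel-style despiking: deviation and MAD scale both taken about the
  # rolling median (robust to the spikes themselves). The scale is floored
  # by the median absolute first difference so that slow trends and the
  # breathing oscillation, whose sample-to-sample excursions are legitimate
  # signal, are never flagged where the local MAD happens to vanish.
  center <- runmed(values, w, endrule = "median")
  dev <- abs(values - center)
  scale <- 1.4826 * runmed(dev, w, endrule = "median")
  floorScale <- 1.4826 * median(abs(diff(values)))
  flag <- dev > k * pmax(scale, floorScale)
  # scale and floor both 0 (locally constant data): any deviation is a spike
  clean <- values
  if (any(flag)) {
    good <- which(!flag)
    if (!length(good))
      stop("all samples flagged; threshold k too small for this series")
    clean[flag] <- approx(time[good], values[good], xout = time[flag],
                          rule = 2)$y
  }
  new("CleanSeries", time = time, values = clean, outlierMask = flag,
      interpolatedCount = as.integer(sum(flag)),
      phaseLabels = character(0))
}

#' Segment a recording into protocol phases
#'
#' Labels each sample pre / breathing / post from the protocol clock and
#' returns the kinetic-fit window (seconds from recording start; default
#' 200--1920 s, inside the stable breathing period). When a recording
#' without protocol metadata is given, a change-point fallback locates the
#' don and doff events as the two largest log-scale level jumps (resistance
#' drops ~100-fold when the mask is donned and recovers at doffing); wave
#' and mode columns are then unavailable.
#'
#' @param time sample times in seconds, or a \code{\link{MaskRecording}}
#'   (whose metadata protocol is then the default).
#' @param protocol a \code{\link{ProtocolSpec}}.
#' @param fitWindow numeric (t_lo, t_hi) for the kinetic fit.
#' @return list(labels = character per sample, fitWindow, lookup =
#'   data.frame(phase, wave, mode) per sample; lookup is NULL under the
#'   change-point fallback).
#' @export
segmentPhases <- function(time, protocol = NULL, fitWindow = c(200, 1920)) {
  rec <- NULL
  if (is(time, "MaskRecording")) {
    rec <- time
    if (is.null(protocol)) protocol <- protocol(time)
    time <- samplingTimes(time)
  }
  if (is.null(protocol)) {
    if (is.null(rec))
      stop("no protocol available: pass one or a recording with metadata")
    # change-point fallback: don = largest downward log jump,
    # doff = largest upward log jump after it
    v <- clipOverflow(colMeans(resistanceMatrix(clipOverflow(rec))))
    jump <- diff(log(v))
    don <- which.min(jump)
    up <- jump
    up[seq_len(don)] <- -Inf
    doff <- which.max(up)
    labels <- rep("post", length(time))
    labels[seq_len(don)] <- "pre"
    labels[(don + 1L):doff] <- "breathing"
    return(list(labels = labels, fitWindow = fitWindow, lookup = NULL))
  }
  span <- max(time)
  if (totalDuration(protocol) > span + 1 / 2)
    stop("protocol span (", totalDuration(protocol),
         " s) exceeds the recording span (", round(span, 2), " s)")
  lk <- .protocolLookup(protocol, time)
  list(labels = lk$phase, fitWindow = fitWindow, lookup = lk)
}

#' Flag defective sensor channels
#'
#' Channels are excluded when, during the breathing phase, they are (i)
#' saturated at/above the overflow limit for more than
#' \code{saturationFraction} of the samples, (ii) essentially flat
#' (near-zero variance: strained connectors freeze the reading), or (iii)
#' non-physical (any finite value <= 0).
#'
#' @param rec a \code{\link{MaskRecording}}.
#' @param protocol protocol used to locate the breathing phase (defaults to
#'   the recording's metadata).
#' @param saturationFraction fraction of breathing-phase samples at the
#'   limit that triggers exclusion.
#' @param flatTol relative (to the channel mean) standard-deviation floor
#'   below which a channel counts as flat.
#' @param overflowLimit logger range limit, ohms.
#' @return data.frame(sensor_id, reason) of excluded channels (zero rows if
#'   all channels are healthy).
#' @export
detectDefectiveSensors <- function(rec, protocol = NULL,
                                   saturationFraction = 0.5,
                                   flatTol = 1e-9, overflowLimit = 1e8) {
  stopifnot(is(rec, "MaskRecording"), nrow(rec) >= 1L)
  if (is.null(protocol)) protocol <- protocol(rec)
  time <- samplingTimes(rec)
  ib <- if (!is.null(protocol))
    which(.protocolLookup(protocol, time)$phase == "breathing")
  else seq_along(time)
  m <- resistanceMatrix(rec)[, ib, drop = FALSE]
  ids <- rownames(m)
  out <- lapply(seq_len(nrow(m)), function(s) {
    x <- m[s, ]
    satFrac <- mean(is.infinite(x) | x >= overflowLimit)
    if (satFrac > saturationFraction)
      return(data.frame(sensor_id = ids[s], reason = "saturated"))
    xf <- x[is.finite(x)]
    if (any(xf <= 0))
      return(data.frame(sensor_id = ids[s], reason = "nonpositive"))
    if (length(xf) < 2L || sd(xf) < flatTol * max(abs(mean(xf)), 1))
      return(data.frame(sensor_id = ids[s], reason = "flatline"))
    NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(sensor_id = character(0),
                               reason = character(0))
  else out
}

#' Array-mean series
#'
#' Per-timepoint arithmetic mean of the resistance over the included
#' channels.
#'
#' @param rec a \code{\link{MaskRecording}}.
#' @param exclude sensor ids to leave out, or the data.frame returned by
#'   \code{\link{detectDefectiveSensors}}.
#' @return an \code{\link{ArrayMeanSeries}}.
#' @export
arrayMean <- function(rec, exclude = character(0)) {
  stopifnot(is(rec, "MaskRecording"))
  if (is.data.frame(exclude)) {
    excludedDf <- exclude
    exclude <- exclude$sensor_id
  } else {
    excludedDf <- data.frame(sensor_id = exclude,
                             reason = rep("user", length(exclude)))
  }
  m <- resistanceMatrix(rec)
  keep <- setdiff(rownames(m), exclude)
  if (!length(keep))
    stop("all channels excluded; cannot form an array mean")
  new("ArrayMeanSeries", time = samplingTimes(rec),
      values = colMeans(m[keep, , drop = FALSE]),
      included = keep, excluded = excludedDf)
}
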