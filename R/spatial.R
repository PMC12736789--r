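# Spatial airflow mapping: per-sensor min-max humidity index, breath-phase
# assignment, inverse-distance-weighted 2D fields over the half-mask
# silhouette, optional 3D shell coordinates, zone summaries.

#' Min-max normalization over an analysis window
#'
#' \code{X' = (X - Xmin) / (Xmax - Xmin)} with the extrema taken over the
#' analysis window, so the window minimum maps to 0 and the maximum to 1.
#'
#' @param values numeric series.
#' @param time optional sample times; required when \code{window} is given.
#' @param window optional (t_lo, t_hi); the series is restricted to it
#'   before normalizing.
#' @return normalized values in [0, 1] (for the windowed samples when a
#'   window is given), with the sample times as the \code{"time"} attribute.
#' @export
minmaxNormalize <- function(values, time = NULL, window = NULL) {
  if (!is.null(window)) {
    if (is.null(time)) stop("window requires sample times")
    sel <- time > window[1] & time < window[2]
    values <- values[sel]
    time <- time[sel]
  }
  if (length(values) < 2L)
    stop("need at least 2 samples to normalize")
  rng <- range(values)
  if (rng[1] == rng[2])
    stop("constant series: min-max normalization undefined")
  out <- (values - rng[1]) / (rng[2] - rng[1])
  attr(out, "time") <- time
  out
}

#' Humidity index from normalized resistance
#'
#' The sensing film's resistance falls as humidity rises, so the humidity
#' index is the complement of the normalized resistance: 1 = wettest
#' observed state (resistance minimum, after exhale), 0 = driest (after
#' inhale).
#'
#' @param xnorm normalized resistance in [0, 1].
#' @return \code{1 - xnorm}.
#' @export
humidityIndex <- function(xnorm) {
  x <- as.numeric(xnorm)
  if (any(x < -1e-9 | x > 1 + 1e-9))
    stop("input must be min-max normalized to [0, 1]")
  out <- 1 - pmin(pmax(x, 0), 1)
  attr(out, "time") <- attr(xnorm, "time")
  out
}

#' Assign inhale/exhale phase per sample
#'
#' On a series detrended of the saturation baseline, exhaled warm moist air
#' drives resistance down and inhaled cooler air lets it recover: samples
#' where the smoothed derivative of resistance is negative are exhale,
#' positive are inhale, and near-zero (within \code{deadband} times the
#' 90th percentile of the absolute derivative, i.e. around the flank
#' turnarounds) are unknown.
#'
#' @param time sample times, seconds.
#' @param detrended resistance with the slow baseline removed, ohms.
#' @param smoothing optional extra smoothing window for the derivative,
#'   seconds; 0 (default) uses the plain central difference, which at 3 Hz
#'   already averages over ~0.7 s -- wider smoothing mainly biases the
#'   flank turnarounds of the asymmetric breath pulse.
#' @param deadband fraction of the derivative scale treated as zero.
#' @return character vector "inhale"/"exhale"/"unknown" per sample.
#' @export
assignBreathPhase <- function(time, detrended, smoothing = 0,
                              deadband = 0.05) {
  stopifnot(length(time) == length(detrended))
  fs <- 1 / median(diff(time))
  w <- .oddWindow(smoothing, fs, minSamples = 1L)
  if (w > 1L) {
    sm <- as.numeric(stats::filter(detrended, rep(1 / w, w), sides = 2))
    na <- is.na(sm)
    sm[na] <- detrended[na]
  } else sm <- detrended
  n <- length(sm)
  d <- rep(NA_real_, n)
  if (n >= 3L)  # central difference: no half-sample lag
    d[2:(n - 1L)] <- (sm[3:n] - sm[1:(n - 2L)]) / (time[3:n] - time[1:(n - 2L)])
  eps <- deadband * quantile(abs(d), 0.9, na.rm = TRUE)
  out <- rep("unknown", length(time))
  out[!is.na(d) & d < -eps] <- "exhale"
  out[!is.na(d) & d > eps] <- "inhale"
  out
}

# Half-mask silhouette polygon in normalized (x, y) coordinates
# (x: front seam -> ear, y: chin -> nose bridge).
.maskSilhouette <- function() {
  cbind(x = c(0.00, 0.45, 0.80, 1.00, 0.95, 0.70, 0.30, 0.00),
        y = c(0.02, 0.00, 0.12, 0.40, 0.72, 0.95, 1.00, 0.95))
}

# even-odd ray casting point-in-polygon (px, py vectors)
.inPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# inverse-distance-weighted interpolation of scattered values onto points
.idw <- function(px, py, sx, sy, sv, power = 2) {
  vapply(seq_along(px), function(i) {
    d2 <- (sx - px[i])^2 + (sy - py[i])^2
    hit <- d2 < 1e-20
    if (any(hit)) return(sv[which(hit)[1]])
    w <- 1 / d2^(power / 2)
    sum(w * sv) / sum(w)
  }, numeric(1))
}

#' Map a half-mask layout onto a 3D shell
#'
#' Parameterizes the half-mask as a quarter-ellipsoid shell: x (seam to
#' ear) sweeps azimuth, y (chin to nose bridge) sweeps elevation.
#'
#' @param x,y normalized layout coordinates in [0, 1].
#' @param side "left" or "right" (mirrors the azimuth).
#' @param semiAxes ellipsoid semi-axes (depth, width, height).
#' @return matrix with columns X, Y, Z.
#' @export
surfaceCoords <- function(x, y, side = "left",
                          semiAxes = c(0.6, 1.0, 0.8)) {
  theta <- (pi / 2) * x          # azimuth from the front seam
  phi <- (y - 0.5) * (pi / 2)    # elevation from mid-face
  sgn <- if (identical(side, "right")) -1 else 1
  cbind(X = semiAxes[1] * cos(phi) * cos(theta),
        Y = sgn * semiAxes[2] * cos(phi) * sin(theta),
        Z = semiAxes[3] * sin(phi))
}

#' Generate spatial humidity-index frames
#'
#' Per requested timestamp: each usable sensor's resistance is min-max
#' normalized over the analysis window, complemented into a humidity index,
#' and interpolated (inverse-distance weighting, default power 2) onto a
#' grid inside the half-mask silhouette, one field per mask side. The frame
#' breath phase comes from \code{\link{assignBreathPhase}} on the detrended
#' array mean of the usable sensors.
#'
#' @param rec a \code{\link{MaskRecording}}.
#' @param times frame timestamps (seconds); snapped to the nearest sample.
#' @param window analysis window for the per-sensor extrema (default the
#'   stable breathing window; pre/post unmasked extremes would crush the
#'   breathing dynamics to a sliver of the scale).
#' @param exclude sensor ids (or a defective-sensor data.frame) to omit.
#' @param gridSize interpolation grid resolution per axis.
#' @param power inverse-distance weighting exponent.
#' @param baselineWindow detrending window (seconds) for phase assignment.
#' @return a \code{\link{SpatialFrameSet}}.
#' @export
makeFrames <- function(rec, times, window = c(200, 1920),
                       exclude = character(0), gridSize = 40L, power = 2,
                       baselineWindow = 30) {
  stopifnot(is(rec, "MaskRecording"))
  if (is.data.frame(exclude)) exclude <- exclude$sensor_id
  tm <- samplingTimes(rec)
  sel <- tm > window[1] & tm < window[2]
  if (!any(sel)) stop("analysis window contains no samples")
  if (any(times < min(tm[sel]) | times > max(tm[sel])))
    stop("requested frame times fall outside the analysis window")
  info <- sensorInfo(rec)
  mat <- resistanceMatrix(rec)[, sel, drop = FALSE]
  wt <- tm[sel]
  use <- setdiff(rownames(mat), exclude)
  # drop constant (un-normalizable) channels
  use <- use[apply(mat[use, , drop = FALSE], 1L, function(v)
    all(is.finite(v)) && min(v) < max(v))]
  if (length(use) < 3L)
    stop("need at least 3 usable sensors to interpolate a field")
  idx <- t(apply(mat[use, , drop = FALSE], 1L, function(v)
    humidityIndex(minmaxNormalize(v))))
  # breath phase from the detrended array mean
  mv <- colMeans(mat[use, , drop = FALSE])
  base <- .rollingMean(mv, .oddWindow(baselineWindow, 1 / median(diff(wt))))
  phaseAll <- assignBreathPhase(wt, mv - base)
  gx <- seq(0, 1, length.out = gridSize)
  gy <- seq(0, 1, length.out = gridSize)
  gpts <- expand.grid(x = gx, y = gy)
  insideMask <- .inPolygon(gpts$x, gpts$y, .maskSilhouette())
  infoUse <- info[match(use, info$sensor_id), ]
  iFrame <- vapply(times, function(t0) which.min(abs(wt - t0)), integer(1))
  frameData <- do.call(rbind, lapply(seq_along(times), function(f) {
    data.frame(time = wt[iFrame[f]], sensor_id = use,
               side = infoUse$side, zone = infoUse$zone,
               x = infoUse$x, y = infoUse$y,
               index = idx[, iFrame[f]], phase = phaseAll[iFrame[f]])
  }))
  rownames(frameData) <- NULL
  grids <- lapply(seq_along(times), function(f) {
    out <- list()
    for (sd in unique(infoUse$side)) {
      ss <- infoUse$side == sd
      field <- rep(NA_real_, nrow(gpts))
      field[insideMask] <- .idw(gpts$x[insideMask], gpts$y[insideMask],
                                infoUse$x[ss], infoUse$y[ss],
                                idx[ss, iFrame[f]], power = power)
      out[[sd]] <- matrix(field, nrow = gridSize, ncol = gridSize,
                          dimnames = NULL)
    }
    out
  })
  new("SpatialFrameSet", frameData = frameData, grids = grids,
      times = wt[iFrame], phases = phaseAll[iFrame], gridX = gx, gridY = gy)
}

#' Zone-level humidity summaries
#'
#' Mean and range of the per-sensor humidity index per layout zone across
#' the frames (optionally restricted to one breath phase).
#'
#' @param frames a \code{\link{SpatialFrameSet}}.
#' @param zones zone labels to report (default: all zones present).
#' @param phase optional phase filter ("inhale"/"exhale").
#' @return data.frame(zone, mean_index, min_index, max_index, n_values);
#'   zones without sensors carry NA.
#' @export
zoneSummaries <- function(frames, zones = NULL, phase = NULL) {
  stopifnot(is(frames, "SpatialFrameSet"), length(frames@times) >= 1L)
  fd <- frames@frameData
  if (!is.null(phase)) fd <- fd[fd$phase %in% phase, , drop = FALSE]
  if (is.null(zones)) zones <- sort(unique(frames@frameData$zone))
  out <- do.call(rbind, lapply(zones, function(z) {
    v <- fd$index[fd$zone == z]
    if (!length(v))
      return(data.frame(zone = z, mean_index = NA_real_,
                        min_index = NA_real_, max_index = NA_real_,
                        n_values = 0L))
    data.frame(zone = z, mean_index = mean(v), min_index = min(v),
               max_index = max(v), n_values = length(v))
  }))
  rownames(out) <- NULL
  out
}
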