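#' Scripted breathing protocol
#'
#' The measurement session schedule: an unmasked pre segment, \code{nWaves}
#' repetitions ("waves") of normal breathing followed by deep breathing, and
#' an unmasked post segment. The defaults encode a 2 min pre recording,
#' 6 waves of 4 min normal + 1 min deep breathing (30 min in total), and a
#' 2 min post recording.
#'
#' @slot preDuration seconds of unmasked recording before the mask is donned.
#' @slot nWaves number of normal+deep repetitions.
#' @slot normalDuration seconds of normal breathing per wave.
#' @slot deepDuration seconds of deep breathing per wave.
#' @slot postDuration seconds of unmasked recording after doffing.
#' @aliases breathingDuration totalDuration
#' @export
setClass("ProtocolSpec",
  slots = c(
    preDuration    = "numeric",
    nWaves         = "integer",
    normalDuration = "numeric",
    deepDuration   = "numeric",
    postDuration   = "numeric"
  )
)

setValidity("ProtocolSpec", function(object) {
  d <- c(object@preDuration, object@normalDuration,
         object@deepDuration, object@postDuration)
  if (length(object@nWaves) != 1L || is.na(object@nWaves) || object@nWaves < 1L)
    return("nWaves must be a single positive integer")
  if (any(!is.finite(d)) || any(d <= 0))
    return("all durations must be finite and > 0")
  TRUE
})

#' @param preDuration,nWaves,normalDuration,deepDuration,postDuration see slots.
#' @return \code{ProtocolSpec()} returns a \code{ProtocolSpec} object.
#' @examples
#' p <- ProtocolSpec()
#' breathingDuration(p)  # 1800 s = 30 min
#' totalDuration(p)      # 2040 s
#' @rdname ProtocolSpec-class
#' @export
ProtocolSpec <- function(preDuration = 120, nWaves = 6L, normalDuration = 240,
                         deepDuration = 60, postDuration = 120) {
  new("ProtocolSpec", preDuration = preDuration, nWaves = as.integer(nWaves),
      normalDuration = normalDuration, deepDuration = deepDuration,
      postDuration = postDuration)
}

#' @rdname ProtocolSpec-class
#' @export
setMethod("breathingDuration", "ProtocolSpec", function(x)
  x@nWaves * (x@normalDuration + x@deepDuration))

#' @rdname ProtocolSpec-class
#' @export
setMethod("totalDuration", "ProtocolSpec", function(x)
  x@preDuration + breathingDuration(x) + x@postDuration)

setMethod("show", "ProtocolSpec", function(object) {
  cat("ProtocolSpec:", object@preDuration, "s pre |",
      object@nWaves, "x (", object@normalDuration, "s normal +",
      object@deepDuration, "s deep ) |", object@postDuration, "s post;",
      "total", totalDuration(object), "s\n")
})

#' Simulator parameters
#'
#' Parameters of the synthetic sensor-array recording generator. The
#' saturation baseline during mask wear is \code{a * exp(-b * t) + c}
#' (t measured from donning): \code{c} is the equilibrium resistance once the
#' membrane has saturated, \code{a} the initial-minus-equilibrium resistance,
#' and \code{b} the decay rate (inverse time constant of moisture transport
#' through the membrane). Breathing adds a zero-mean oscillation whose
#' peak-to-trough amplitude is \code{ampNormal} (or \code{ampDeep}) times the
#' sensor's zone gain; resistance falls on exhale because the sensing film's
#' resistance decreases as humidity rises.
#'
#' @slot a ohms; baseline decay amplitude (> 0).
#' @slot b 1/seconds; baseline decay rate (> 0).
#' @slot c ohms; equilibrium (saturation) resistance (> 0).
#' @slot ampNormal,ampDeep ohms; peak-to-trough breathing amplitudes
#'   (\code{ampDeep > ampNormal}).
#' @slot rrNormal,rrDeep breaths/min for the two instructed modes
#'   (\code{rrNormal > rrDeep}).
#' @slot rrJitter fractional standard deviation of the lognormal inter-breath
#'   interval jitter.
#' @slot exhaleFraction fraction of each breath spent exhaling (resistance
#'   falling); the within-breath resistance trough sits at this fraction.
#' @slot noiseSigma ohms; additive Gaussian measurement noise s.d.
#' @slot unmaskedLevel ohms; dry-sensor resistance while the mask is not worn
#'   (may exceed the logger range).
#' @slot overflowLimit ohms; maximum resistance the logger can register;
#'   readings above it are recorded as overflow markers.
#' @slot artifactMagnitude dimensionless; motion-artifact spike factor at
#'   don/doff (spikes multiply/divide the local level by 1 + magnitude).
#' @slot artifactDuration seconds of artifact after each don/doff event.
#' @slot zoneGains named multipliers on breathing amplitude per layout zone.
#' @slot seed integer RNG seed; recordings are bit-reproducible given the seed.
#' @export
setClass("SimulationParams",
  slots = c(
    a = "numeric", b = "numeric", c = "numeric",
    ampNormal = "numeric", ampDeep = "numeric",
    rrNormal = "numeric", rrDeep = "numeric",
    rrJitter = "numeric", exhaleFraction = "numeric",
    noiseSigma = "numeric", unmaskedLevel = "numeric",
    overflowLimit = "numeric",
    artifactMagnitude = "numeric", artifactDuration = "numeric",
    zoneGains = "numeric", seed = "integer"
  )
)

setValidity("SimulationParams", function(object) {
  msg <- character(0)
  num1 <- function(v) length(v) == 1L && is.finite(v)
  for (nm in c("a", "b", "c", "ampNormal", "ampDeep", "rrNormal", "rrDeep",
               "rrJitter", "exhaleFraction", "noiseSigma", "unmaskedLevel",
               "overflowLimit", "artifactMagnitude", "artifactDuration"))
    if (!num1(slot(object, nm)))
      msg <- c(msg, paste0(nm, " must be a single finite number"))
  if (length(msg)) return(msg)
  if (object@a <= 0 || object@b <= 0 || object@c <= 0)
    msg <- c(msg, "a, b, c must all be > 0")
  if (object@ampNormal < 0 || object@ampDeep <= object@ampNormal)
    msg <- c(msg, "need ampDeep > ampNormal >= 0")
  if (object@rrNormal <= object@rrDeep || object@rrDeep <= 0)
    msg <- c(msg, "need rrNormal > rrDeep > 0")
  if (object@overflowLimit <= 0)
    msg <- c(msg, "overflowLimit must be > 0")
  if (object@exhaleFraction <= 0 || object@exhaleFraction >= 1)
    msg <- c(msg, "exhaleFraction must be in (0, 1)")
  if (is.null(names(object@zoneGains)) || any(object@zoneGains < 0))
    msg <- c(msg, "zoneGains must be a named non-negative vector")
  if (length(msg)) msg else TRUE
})

#' @param a,b,c,ampNormal,ampDeep,rrNormal,rrDeep,rrJitter,exhaleFraction see slots.
#' @param noiseSigma,unmaskedLevel,overflowLimit see slots.
#' @param artifactMagnitude,artifactDuration,zoneGains,seed see slots.
#' @return \code{SimulationParams()} returns a \code{SimulationParams} object.
#' @details Default baseline coefficients (a = 9e5, b = 2e-3, c = 1e5 on the
#'   ohm scale) give a ~500 s saturation time constant within a 10^5--10^8
#'   resistance range; default amplitudes (140/480 ohms at the mouth zone)
#'   produce array-mean breathing amplitudes of roughly 70 (normal) and 240
#'   (deep) ohms under the default layout.
#' @rdname SimulationParams-class
#' @export
SimulationParams <- function(a = 9e5, b = 2e-3, c = 1e5,
                             ampNormal = 140, ampDeep = 480,
                             rrNormal = 18, rrDeep = 8,
                             rrJitter = 0.05, exhaleFraction = 0.35,
                             noiseSigma = 20, unmaskedLevel = 5e8,
                             overflowLimit = 1e8,
                             artifactMagnitude = 3, artifactDuration = 1.5,
                             zoneGains = c(mouth_nose = 1.0, bottom = 0.5,
                                           side = 0.3, top = 0.1),
                             seed = 1L) {
  new("SimulationParams", a = a, b = b, c = c,
      ampNormal = ampNormal, ampDeep = ampDeep,
      rrNormal = rrNormal, rrDeep = rrDeep,
      rrJitter = rrJitter, exhaleFraction = exhaleFraction,
      noiseSigma = noiseSigma, unmaskedLevel = unmaskedLevel,
      overflowLimit = overflowLimit,
      artifactMagnitude = artifactMagnitude,
      artifactDuration = artifactDuration,
      zoneGains = zoneGains, seed = as.integer(seed))
}

setMethod("show", "SimulationParams", function(object) {
  cat("SimulationParams: baseline a=", object@a, " b=", object@b,
      " c=", object@c, "\n  breathing ", object@rrNormal, "/",
      object@rrDeep, " bpm, amplitudes ", object@ampNormal, "/",
      object@ampDeep, " ohm, noise sd ", object@noiseSigma,
      " ohm, seed ", object@seed, "\n", sep = "")
})

#' Sensor layout on the mask
#'
#' Positions of the 19 printed humidity sensors on each mask side, with zone
#' labels. Coordinates are normalized to the half-mask sheet: x = 0 at the
#' front seam, x = 1 at the ear strap, y = 0 at the chin, y = 1 at the nose
#' bridge. Zones follow the airflow regions of a worn mask:
#' \code{mouth_nose} (below the nose / in front of the mouth, strongest
#' breathing response), \code{top} (nose bridge, minimal response on a
#' well-fitted mask), \code{bottom} (chin, exhaled air flows down and out)
#' and \code{side} (cheeks, moderate response).
#'
#' @slot info data.frame with columns \code{sensor_id}, \code{side}
#'   ("left"/"right"), \code{x}, \code{y} in [0, 1] and \code{zone}.
#' @export
setClass("SensorLayout", slots = c(info = "data.frame"))

setValidity("SensorLayout", function(object) {
  info <- object@info
  need <- c("sensor_id", "side", "x", "y", "zone")
  if (!all(need %in% names(info)))
    return(paste("layout needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(info$sensor_id))
    return("sensor_id values must be unique")
  if (!all(table(info$side) == 19L))
    return("each mask side must carry exactly 19 sensors")
  if (any(info$x < 0 | info$x > 1 | info$y < 0 | info$y > 1))
    return("coordinates must lie in [0, 1]")
  if (any(is.na(info$zone) | !nzchar(info$zone)))
    return("every sensor needs a zone label")
  TRUE
})

#' @param info see slot.
#' @return \code{SensorLayout()} returns a \code{SensorLayout} object.
#' @rdname SensorLayout-class
#' @export
SensorLayout <- function(info) new("SensorLayout", info = as.data.frame(info))

setMethod("show", "SensorLayout", function(object) {
  cat("SensorLayout:", nrow(object@info), "sensors on",
      length(unique(object@info$side)), "side(s); zones:",
      paste(names(table(object@info$zone)), table(object@info$zone),
            sep = ":", collapse = " "), "\n")
})

#' Default two-sided 19-sensor mask layout
#'
#' @param sides which mask sides to include.
#' @return A \code{SensorLayout} with 19 sensors per requested side
#'   (5 mouth_nose, 4 top, 5 bottom, 5 side).
#' @export
defaultSensorLayout <- function(sides = c("left", "right")) {
  one <- data.frame(
    x = c(0.10, 0.25, 0.40, 0.20, 0.35,        # mouth_nose
          0.15, 0.35, 0.55, 0.75,              # top
          0.10, 0.28, 0.46, 0.64, 0.80,        # bottom
          0.60, 0.72, 0.85, 0.68, 0.82),       # side
    y = c(0.55, 0.60, 0.55, 0.42, 0.45,
          0.92, 0.88, 0.84, 0.80,
          0.10, 0.12, 0.15, 0.18, 0.22,
          0.60, 0.52, 0.45, 0.35, 0.62),
    zone = rep(c("mouth_nose", "top", "bottom", "side"), c(5L, 4L, 5L, 5L))
  )
  info <- do.call(rbind, lapply(sides, function(s) {
    data.frame(
      sensor_id = sprintf("%s%02d", toupper(substr(s, 1, 1)), seq_len(19L)),
      side = s, one
    )
  }))
  SensorLayout(info)
}

#' Multichannel mask resistance recording
#'
#' A \code{SummarizedExperiment} holding one resistance assay with sensors as
#' rows and timepoints as columns. \code{rowData} carries the sensor layout
#' (id, side, x, y, zone), \code{colData} the sampling times in seconds, and
#' \code{metadata} the ambient conditions, the breathing protocol and -- for
#' simulated recordings -- the generator's parameters and breath truth log.
#' Overflow logger readings are carried as \code{Inf} until
#' \code{\link{clipOverflow}} is applied.
#'
#' @aliases resistanceMatrix samplingTimes sensorInfo protocol
#'   ambientConditions breathLog
#' @export
setClass("MaskRecording", contains = "SummarizedExperiment")

setValidity("MaskRecording", function(object) {
  if (!"resistance" %in% SummarizedExperiment::assayNames(object))
    return("needs a 'resistance' assay")
  tm <- object$time_s
  if (is.null(tm)) return("colData must carry time_s")
  if (length(tm) > 1L && any(diff(tm) <= 0))
    return("time_s must be strictly increasing")
  v <- SummarizedExperiment::assay(object, "resistance")
  if (any(v[is.finite(v)] <= 0))
    return("finite resistance values must be > 0")
  TRUE
})

#' @param resistance numeric matrix, sensors x timepoints, ohms
#'   (\code{Inf} marks overflow readings).
#' @param time numeric vector of sampling times in seconds (nominally 3 Hz).
#' @param layout a \code{SensorLayout} (or data.frame in its \code{info}
#'   shape) matching the matrix rows by \code{sensor_id}.
#' @param ambientTemp,ambientRH ambient temperature (deg C) and relative
#'   humidity (\%) during the session.
#' @param protocol a \code{ProtocolSpec} or NULL.
#' @param breathLog,params simulation truth (breath schedule data.frame and
#'   \code{SimulationParams}) for synthetic recordings, else NULL.
#' @return \code{MaskRecording()} returns a \code{MaskRecording} object.
#' @rdname MaskRecording-class
#' @export
MaskRecording <- function(resistance, time, layout,
                          ambientTemp = NA_real_, ambientRH = NA_real_,
                          protocol = NULL, breathLog = NULL, params = NULL) {
  if (is(layout, "SensorLayout")) layout <- layout@info
  layout <- as.data.frame(layout)
  if (is.null(rownames(resistance))) rownames(resistance) <- layout$sensor_id
  layout <- layout[match(rownames(resistance), layout$sensor_id), , drop = FALSE]
  if (anyNA(layout$sensor_id))
    stop("layout does not cover all matrix rows")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(resistance = resistance),
    rowData = S4Vectors::DataFrame(layout, row.names = layout$sensor_id),
    colData = S4Vectors::DataFrame(time_s = time),
    metadata = list(ambient_temp_c = ambientTemp, ambient_rh_pct = ambientRH,
                    protocol = protocol, breath_log = breathLog,
                    sim_params = params)
  )
  new("MaskRecording", se)
}

#' @rdname MaskRecording-class
#' @export
setMethod("resistanceMatrix", "MaskRecording", function(x)
  SummarizedExperiment::assay(x, "resistance"))

#' @rdname MaskRecording-class
#' @export
setMethod("samplingTimes", "MaskRecording", function(x) x$time_s)

#' @rdname MaskRecording-class
#' @export
setMethod("sensorInfo", "MaskRecording", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname MaskRecording-class
#' @export
setMethod("protocol", "MaskRecording", function(x)
  S4Vectors::metadata(x)$protocol)

#' @rdname MaskRecording-class
#' @export
setMethod("ambientConditions", "MaskRecording", function(x) {
  md <- S4Vectors::metadata(x)
  c(temp_c = md$ambient_temp_c, rh_pct = md$ambient_rh_pct)
})

#' @rdname MaskRecording-class
#' @export
setMethod("breathLog", "MaskRecording", function(x)
  S4Vectors::metadata(x)$breath_log)

setMethod("show", "MaskRecording", function(object) {
  tm <- samplingTimes(object)
  cat("MaskRecording:", nrow(object), "sensors x", ncol(object),
      "samples;", sprintf("%.1f-%.1f s", min(tm), max(tm)), "\n")
  amb <- ambientConditions(object)
  cat("  ambient:", amb[["temp_c"]], "degC /", amb[["rh_pct"]], "% RH;",
      "overflow samples:", sum(!is.finite(resistanceMatrix(object))), "\n")
  if (!is.null(protocol(object))) { cat("  "); show(protocol(object)) }
})

#' Cleaned single-channel series
#'
#' A resistance series after motion-outlier removal: flagged samples have
#' been replaced by linear interpolation between their nearest unflagged
#' neighbours.
#'
#' @slot time seconds.
#' @slot values ohms, finite.
#' @slot outlierMask TRUE where the original sample was replaced.
#' @slot interpolatedCount number of replaced samples.
#' @slot phaseLabels per-sample "pre"/"breathing"/"post" labels (may be
#'   empty until \code{\link{segmentPhases}} is applied).
#' @export
setClass("CleanSeries",
  slots = c(time = "numeric", values = "numeric", outlierMask = "logical",
            interpolatedCount = "integer", phaseLabels = "character"))

setValidity("CleanSeries", function(object) {
  if (length(object@time) != length(object@values) ||
      length(object@time) != length(object@outlierMask))
    return("time, values and outlierMask must have equal length")
  if (any(!is.finite(object@values)))
    return("cleaned values must be finite")
  if (length(object@phaseLabels) &&
      length(object@phaseLabels) != length(object@time))
    return("phaseLabels must be empty or per-sample")
  TRUE
})

setMethod("show", "CleanSeries", function(object) {
  cat("CleanSeries:", length(object@time), "samples,",
      object@interpolatedCount, "interpolated\n")
})

#' Array-mean series
#'
#' Per-timepoint arithmetic mean of the included sensor channels, with the
#' exclusion log.
#'
#' @slot time seconds.
#' @slot values ohms.
#' @slot included sensor ids entering the mean.
#' @slot excluded data.frame(sensor_id, reason) of excluded channels.
#' @export
setClass("ArrayMeanSeries",
  slots = c(time = "numeric", values = "numeric",
            included = "character", excluded = "data.frame"))

setMethod("show", "ArrayMeanSeries", function(object) {
  cat("ArrayMeanSeries:", length(object@time), "samples; mean of",
      length(object@included), "sensors (", nrow(object@excluded),
      "excluded )\n")
})

#' Exponential saturation fit
#'
#' Result of fitting \code{R(t) = a * exp(-b * t) + c} (t referenced to the
#' window start) on the stable breathing window, together with the
#' two-regime log decomposition: for small t, \code{log(R) ~ log(a) - b t}
#' (early straight line); once the exponential has decayed, \code{log(R) ~
#' log(c)} (late saturation level). Natural logarithms throughout.
#'
#' @slot a,b,c fitted coefficients (ohms, 1/s, ohms), all positive.
#' @slot rSquared coefficient of determination on the window.
#' @slot window (t_lo, t_hi) seconds from recording start.
#' @slot logInterceptEarly,logSlopeEarly early-segment OLS intercept
#'   (log-ohms at window start) and slope (1/s; the slope estimates -b).
#' @slot logLevelLate mean log-resistance of the late segment (estimates
#'   log(c) at saturation).
#' @slot breakpoint seconds; split between the two regimes.
#' @slot nPoints samples used.
#' @export
setClass("ExpFitResult",
  slots = c(a = "numeric", b = "numeric", c = "numeric",
            rSquared = "numeric", window = "numeric",
            logInterceptEarly = "numeric", logSlopeEarly = "numeric",
            logLevelLate = "numeric", breakpoint = "numeric",
            nPoints = "integer"))

setValidity("ExpFitResult", function(object) {
  if (object@a <= 0 || object@b <= 0 || object@c <= 0)
    return("a, b, c must be > 0")
  if (object@rSquared < 0 || object@rSquared > 1)
    return("rSquared must lie in [0, 1]")
  if (object@breakpoint <= object@window[1] ||
      object@breakpoint >= object@window[2])
    return("breakpoint must lie strictly inside the window")
  TRUE
})

setMethod("show", "ExpFitResult", function(object) {
  cat(sprintf(
    "ExpFitResult: R(t) = %.4g * exp(-%.4g t) + %.4g   (R^2 = %.4f)\n",
    object@a, object@b, object@c, object@rSquared))
  cat(sprintf("  window %g-%g s, breakpoint %.1f s, %d points\n",
              object@window[1], object@window[2], object@breakpoint,
              object@nPoints))
  cat(sprintf("  log regimes: early %.4f %+.5f t | late level %.4f\n",
              object@logInterceptEarly, object@logSlopeEarly,
              object@logLevelLate))
})

#' Per-session breathing summary
#'
#' Per-wave, per-mode mean respiration rate and amplitude, plus the
#' session-level mean differences between normal and deep breathing. Wave 1
#' is never included in the session-level means (the membrane is still
#' absorbing moisture there); waves missing either mode are skipped.
#'
#' @slot waves data.frame(wave, mode, mean_rr, mean_amplitude, n_breaths,
#'   available), one row per wave x mode.
#' @slot deltaRR breaths/min; mean over usable waves (2..n, both modes
#'   present) of normal mean RR minus deep mean RR.
#' @slot deltaAmp ohms; same for amplitude (NA when amplitudes absent).
#' @slot wavesUsed wave indices entering the deltas.
#' @export
setClass("SessionSummary",
  slots = c(waves = "data.frame", deltaRR = "numeric", deltaAmp = "numeric",
            wavesUsed = "integer"))

setMethod("show", "SessionSummary", function(object) {
  cat("SessionSummary over", length(unique(object@waves$wave)), "waves\n")
  w <- object@waves
  for (i in sort(unique(w$wave))) {
    rn <- w[w$wave == i & w$mode == "normal", ]
    rd <- w[w$wave == i & w$mode == "deep", ]
    cat(sprintf("  W%d: normal %5.1f bpm (n=%2d) | deep %5.1f bpm (n=%2d)\n",
                i, rn$mean_rr, rn$n_breaths, rd$mean_rr, rd$n_breaths))
  }
  cat(sprintf("  mean RR difference (waves %s): %.2f bpm\n",
              paste(object@wavesUsed, collapse = ","), object@deltaRR))
  if (is.finite(object@deltaAmp))
    cat(sprintf("  mean amplitude difference: %.1f ohm\n", object@deltaAmp))
})

#' Spatial humidity-index frames
#'
#' Per-sensor humidity index (1 = wettest observed state, after exhale;
#' 0 = driest, after inhale) at selected timestamps, plus an
#' inverse-distance-weighted 2D field over the half-mask silhouette per
#' frame and side.
#'
#' @slot frameData long data.frame(time, sensor_id, side, zone, x, y, index,
#'   phase).
#' @slot grids list (one per frame) of per-side interpolated matrices
#'   (NA outside the mask silhouette).
#' @slot times frame timestamps, seconds.
#' @slot phases per-frame breath phase ("inhale"/"exhale"/"unknown").
#' @slot gridX,gridY grid axis coordinates.
#' @export
setClass("SpatialFrameSet",
  slots = c(frameData = "data.frame", grids = "list", times = "numeric",
            phases = "character", gridX = "numeric", gridY = "numeric"))

setMethod("show", "SpatialFrameSet", function(object) {
  cat("SpatialFrameSet:", length(object@times), "frames,",
      length(unique(object@frameData$sensor_id)), "sensors; phases:",
      paste(names(table(object@phases)), table(object@phases),
            sep = ":", collapse = " "), "\n")
})

#' Full-session analysis report
#'
#' Output of \code{\link{runPipeline}}: breathing summary, kinetic fit, zone
#' summaries, the sensor exclusion log, ambient metadata and per-stage
#' counts.
#'
#' @slot session a \code{SessionSummary}.
#' @slot fit an \code{ExpFitResult}.
#' @slot zones zone-summary data.frame.
#' @slot exclusions data.frame(sensor_id, reason).
#' @slot ambient named numeric (temp_c, rh_pct).
#' @slot counts named list of per-stage sample/event counts.
#' @export
setClass("SessionReport",
  slots = c(session = "SessionSummary", fit = "ExpFitResult",
            zones = "data.frame", exclusions = "data.frame",
            ambient = "numeric", counts = "list"))

setMethod("show", "SessionReport", function(object) {
  cat("SessionReport\n")
  cat("  ambient:", object@ambient[["temp_c"]], "degC /",
      object@ambient[["rh_pct"]], "% RH\n")
  cat("  sensors excluded:", nrow(object@exclusions), "\n")
  show(object@fit)
  show(object@session)
})
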