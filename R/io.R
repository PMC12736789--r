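# File formats, run configuration and the end-to-end pipeline
# (simulate/read -> preprocess -> breaths -> kinetics -> spatial -> report).

#' Read a recording from the data-logger CSV dialect
#'
#' Parses the format written by \code{\link{writeRecordingCSV}}: optional
#' \code{# key=value} header comments (ambient_temp_c, ambient_rh_pct,
#' protocol as JSON), a header row \code{time_s,<sensor ids...>}, and the
#' literal token \code{overflow} for out-of-range readings (restored as
#' \code{Inf} markers until \code{\link{clipOverflow}}).
#'
#' @param path CSV file path.
#' @param layout optional \code{\link{SensorLayout}} supplying positions and
#'   zones; without one, sides are inferred from the L/R id prefix and
#'   zones are unknown.
#' @return a \code{\link{MaskRecording}}.
#' @export
readRecordingCSV <- function(path, layout = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  isComment <- grepl("^#", lines)
  meta <- list()
  for (cl in lines[isComment]) {
    kv <- sub("^#\\s*", "", cl)
    key <- sub("=.*$", "", kv)
    val <- sub("^[^=]*=", "", kv)
    meta[[key]] <- val
  }
  body <- lines[!isComment]
  if (!length(body)) stop("file has no data rows")
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  if (header[1] != "time_s")
    stop("line ", which(!isComment)[1], ": first column must be time_s")
  if (length(header) < 2L) stop("no sensor columns found")
  cells <- strsplit(body[-1], ",", fixed = TRUE)
  bad <- which(lengths(cells) != length(header))
  if (length(bad))
    stop("line ", which(!isComment)[bad[1] + 1L], ": expected ",
         length(header), " fields, found ", lengths(cells)[bad[1]])
  tab <- matrix(unlist(cells), nrow = length(cells), byrow = TRUE)
  parseNum <- function(v, what, col) {
    out <- suppressWarnings(as.numeric(v))
    out[v == "overflow"] <- Inf
    badRow <- which(is.na(out) & v != "overflow")
    if (length(badRow))
      stop("line ", which(!isComment)[badRow[1] + 1L], ", column ", col,
           ": unparseable ", what, " value '", v[badRow[1]], "'")
    out
  }
  time <- parseNum(tab[, 1], "time", "time_s")
  if (any(!is.finite(time)))
    stop("time column contains non-finite values")
  if (length(time) > 1L && any(diff(time) <= 0))
    stop("line ", which(!isComment)[which(diff(time) <= 0)[1] + 2L],
         ": time_s is not strictly increasing")
  ids <- header[-1]
  mat <- matrix(NA_real_, nrow = length(ids), ncol = length(time),
                dimnames = list(ids, NULL))
  for (j in seq_along(ids))
    mat[j, ] <- parseNum(tab[, j + 1L], "resistance", ids[j])
  if (!is.null(layout)) {
    info <- if (is(layout, "SensorLayout")) layout@info else layout
    info <- info[match(ids, info$sensor_id), ]
    if (anyNA(info$sensor_id))
      stop("layout does not cover sensors: ",
           paste(setdiff(ids, info$sensor_id), collapse = ", "))
  } else {
    info <- data.frame(sensor_id = ids,
                       side = ifelse(grepl("^R", ids), "right", "left"),
                       x = NA_real_, y = NA_real_, zone = "unknown")
  }
  prot <- NULL
  if (!is.null(meta$protocol)) {
    pl <- jsonlite::fromJSON(meta$protocol)
    prot <- ProtocolSpec(pl$preDuration, pl$nWaves, pl$normalDuration,
                         pl$deepDuration, pl$postDuration)
  }
  asNum <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  rec <- SummarizedExperiment::SummarizedExperiment(
    assays = list(resistance = mat),
    rowData = S4Vectors::DataFrame(info, row.names = info$sensor_id),
    colData = S4Vectors::DataFrame(time_s = time),
    metadata = list(ambient_temp_c = asNum(meta$ambient_temp_c),
                    ambient_rh_pct = asNum(meta$ambient_rh_pct),
                    protocol = prot, breath_log = NULL, sim_params = NULL))
  new("MaskRecording", rec)
}

#' Default run configuration
#'
#' A fully populated pipeline configuration as a named list; override
#' fields as needed and validate with \code{\link{validateRunConfig}}.
#' \code{input} may be a CSV path or NULL to simulate (the
#' \code{simulation} sub-list then maps to \code{\link{SimulationParams}}).
#'
#' @param seed RNG seed for a simulated input.
#' @return a named list of pipeline settings.
#' @export
runConfigDefaults <- function(seed = 1L) {
  list(
    input = NULL,
    seed = as.integer(seed),
    protocol = list(preDuration = 120, nWaves = 6L, normalDuration = 240,
                    deepDuration = 60, postDuration = 120),
    simulation = list(),
    preprocess = list(overflowLimit = 1e8, window = 30, k = 5,
                      saturationFraction = 0.5),
    breath = list(minPeriod = 2, minDt = 1, rrThreshold = 15),
    kinetics = list(window = c(200, 1920)),
    spatial = list(frameInterval = c(1500, 1620), frameStep = 1 / 3,
                   power = 2, gridSize = 40L),
    output_dir = NULL
  )
}

#' Validate a run configuration
#'
#' Checks structure and value ranges before any pipeline stage runs;
#' unknown fields are rejected so that typos fail loudly.
#'
#' @param config a configuration list (see \code{\link{runConfigDefaults}}).
#' @return the completed configuration (defaults filled in), invisibly
#'   usable; errors describe the offending field.
#' @export
validateRunConfig <- function(config) {
  def <- runConfigDefaults()
  extra <- setdiff(names(config), names(def))
  if (length(extra))
    stop("unknown config field(s): ", paste(extra, collapse = ", "))
  for (nm in names(def))
    if (is.null(config[[nm]]) && !nm %in% c("input", "output_dir"))
      config[[nm]] <- def[[nm]]
  for (nm in c("preprocess", "breath", "kinetics", "spatial", "protocol")) {
    extra <- setdiff(names(config[[nm]]), names(def[[nm]]))
    if (length(extra))
      stop("unknown ", nm, " config field(s): ", paste(extra, collapse = ", "))
    miss <- setdiff(names(def[[nm]]), names(config[[nm]]))
    config[[nm]][miss] <- def[[nm]][miss]
  }
  p <- config$preprocess
  if (p$overflowLimit <= 0) stop("preprocess.overflowLimit must be > 0")
  if (p$k <= 0) stop("preprocess.k must be > 0")
  kw <- config$kinetics$window
  if (length(kw) != 2L || kw[1] >= kw[2])
    stop("kinetics.window must be (t_lo, t_hi) with t_lo < t_hi")
  if (config$breath$minDt <= 0) stop("breath.minDt must be > 0")
  if (!is.null(config$input) && !file.exists(config$input))
    stop("input file not found: ", config$input)
  config$seed <- as.integer(config$seed)
  config
}

#' Read a run configuration from JSON
#'
#' @param path JSON file path.
#' @return the validated configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validateRunConfig(cfg)
}

.protocolFromConfig <- function(pl) {
  ProtocolSpec(pl$preDuration, pl$nWaves, pl$normalDuration,
               pl$deepDuration, pl$postDuration)
}

# deterministic CSV writer (fixed field order, no timestamps/row names)
.writeTable <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Chains simulate/read, overflow clipping, phase segmentation,
#' defective-sensor exclusion, array mean, motion-outlier removal, breath
#' detection and anomaly screening, per-wave summaries with normal/deep
#' classification, the exponential kinetic fit and the spatial frames, and
#' (when \code{output_dir} is set) writes the machine-readable report
#' tables plus the resolved configuration. Outputs are deterministic: the
#' same configuration and seed reproduce every file byte for byte.
#'
#' @param config configuration list (see \code{\link{runConfigDefaults}});
#'   validated before any stage runs.
#' @param verbose print per-stage counts.
#' @return a \code{\link{SessionReport}}.
#' @export
runPipeline <- function(config = runConfigDefaults(), verbose = FALSE) {
  config <- validateRunConfig(config)
  prot <- .protocolFromConfig(config$protocol)
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  log <- list()
  say <- function(...) if (verbose) message(...)

  rec <- stage("input", {
    if (!is.null(config$input)) readRecordingCSV(config$input)
    else {
      sim <- config$simulation
      sim$seed <- config$seed
      params <- do.call(SimulationParams, sim)
      simulateRecording(params, protocol = prot)
    }
  })
  if (!is.null(protocol(rec))) prot <- protocol(rec)
  log$raw_samples <- ncol(rec)
  log$sensors <- nrow(rec)
  say("input: ", log$sensors, " sensors x ", log$raw_samples, " samples")

  lim <- config$preprocess$overflowLimit
  raw <- resistanceMatrix(rec)
  log$clipped_values <- sum(is.infinite(raw) | raw > lim)
  recC <- stage("clip", clipOverflow(rec, limit = lim))

  seg <- stage("segment", segmentPhases(recC, prot,
                                        fitWindow = config$kinetics$window))
  excl <- stage("defective", detectDefectiveSensors(
    recC, prot, saturationFraction = config$preprocess$saturationFraction,
    overflowLimit = lim))
  log$sensors_excluded <- nrow(excl)
  say("excluded sensors: ", nrow(excl))

  am <- stage("array_mean", arrayMean(recC, excl))
  clean <- stage("outliers", removeMotionOutliers(
    am@time, am@values, window = config$preprocess$window,
    k = config$preprocess$k, labels = seg$labels))
  log$outliers_interpolated <- clean@interpolatedCount
  say("interpolated outliers: ", clean@interpolatedCount)

  events <- stage("breaths", {
    ib <- seg$labels == "breathing"
    ev <- detectBreaths(clean@time[ib], clean@values[ib],
                        minPeriod = config$breath$minPeriod)
    screenAnomalies(ev, minDt = config$breath$minDt)
  })
  log$breaths_detected <- nrow(events)
  log$breaths_flagged <- sum(events$anomaly)
  say("breaths: ", nrow(events), " (", sum(events$anomaly), " flagged)")

  session <- stage("waves", summarizeWaves(events, prot))
  fit <- stage("kinetics", fitExponential(clean@time, clean@values,
                                          window = config$kinetics$window))
  frames <- stage("spatial", {
    fi <- config$spatial$frameInterval
    makeFrames(recC, times = seq(fi[1], fi[2], by = config$spatial$frameStep),
               window = config$kinetics$window, exclude = excl,
               gridSize = config$spatial$gridSize,
               power = config$spatial$power)
  })
  zones <- zoneSummaries(frames)
  log$frames <- length(frames@times)

  report <- new("SessionReport", session = session, fit = fit,
                zones = zones, exclusions = excl,
                ambient = ambientConditions(recC), counts = log)

  if (!is.null(config$output_dir)) {
    out <- config$output_dir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(config, file.path(out, "resolved_config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    wv <- session@waves
    wv$mean_rr <- round(wv$mean_rr, 1)
    wv$mean_amplitude <- round(wv$mean_amplitude, 1)
    .writeTable(wv, file.path(out, "wave_summary.csv"))
    .writeTable(data.frame(a = fit@a, b = fit@b, c = fit@c,
                           r_squared = fit@rSquared,
                           window_lo = fit@window[1],
                           window_hi = fit@window[2],
                           breakpoint = fit@breakpoint),
                file.path(out, "fit_coefficients.csv"))
    .writeTable(zones, file.path(out, "zone_summary.csv"))
    .writeTable(events, file.path(out, "breath_events.csv"))
    .writeTable(frames@frameData[, c("time", "sensor_id", "index", "phase")],
                file.path(out, "frames.csv"))
    .writeTable(excl, file.path(out, "exclusions.csv"))
    txt <- c("maskflow session report",
             sprintf("ambient: %s degC / %s %% RH",
                     format(report@ambient[["temp_c"]]),
                     format(report@ambient[["rh_pct"]])),
             sprintf("sensors: %d (%d excluded)", log$sensors,
                     nrow(excl)),
             sprintf("fit: a=%.6g b=%.6g c=%.6g R2=%.4f",
                     fit@a, fit@b, fit@c, fit@rSquared),
             sprintf("mean RR difference: %.2f bpm over waves %s",
                     session@deltaRR,
                     paste(session@wavesUsed, collapse = ",")),
             sprintf("counts: %s",
                     paste(names(log), unlist(log), sep = "=",
                           collapse = " ")))
    writeLines(txt, file.path(out, "summary.txt"))
  }
  report
}

#' Per-day ambient summaries
#'
#' Mean ambient temperature and relative humidity per group (e.g. per
#' session day) from a conditions table.
#'
#' @param conditions data.frame with columns \code{temp_c}, \code{rh_pct}
#'   and the grouping column.
#' @param by name of the grouping column (default "day").
#' @return data.frame(group, mean_temp_c, mean_rh_pct, n).
#' @export
summarizeAmbient <- function(conditions, by = "day") {
  stopifnot(all(c("temp_c", "rh_pct", by) %in% names(conditions)))
  out <- do.call(rbind, lapply(split(conditions, conditions[[by]]),
    function(g) data.frame(group = g[[by]][1],
                           mean_temp_c = mean(g$temp_c),
                           mean_rh_pct = mean(g$rh_pct),
                           n = nrow(g))))
  rownames(out) <- NULL
  names(out)[1] <- by
  out
}
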