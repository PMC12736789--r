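# Shared fixtures: simulated sessions are cached per parameter set so that
# multiple test files can reuse them without re-simulating.

.fixtureCache <- new.env(parent = emptyenv())

# simulate + clip + segment + array mean + clean, cached by key
preprocessedSession <- function(seed = 1, params = NULL) {
  key <- if (is.null(params)) paste0("s", seed) else
    paste0("s", seed, "_", paste(deparse(params), collapse = ""))
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  if (is.null(params)) params <- SimulationParams(seed = seed)
  rec <- clipOverflow(simulateRecording(params))
  seg <- segmentPhases(rec)
  excl <- detectDefectiveSensors(rec)
  am <- arrayMean(rec, excl)
  clean <- removeMotionOutliers(am@time, am@values, labels = seg$labels)
  out <- list(params = params, rec = rec, seg = seg, excl = excl,
              am = am, clean = clean)
  .fixtureCache[[key]] <- out
  out
}

# detected + screened breath events on the breathing segment
sessionEvents <- function(sess) {
  ib <- sess$seg$labels == "breathing"
  screenAnomalies(detectBreaths(sess$clean@time[ib], sess$clean@values[ib]))
}

# per-wave mean RR from the generator's own breath log, using the same
# peak-to-peak (trough-to-trough) interval convention as the detector and
# dropping mode-boundary-straddling intervals: the brute-force oracle for
# recovery checks
truthWaveMeans <- function(lg) {
  n <- nrow(lg)
  dt <- diff(lg$trough_time)
  keep <- lg$mode[-n] == lg$mode[-1] & lg$wave[-n] == lg$wave[-1]
  df <- data.frame(wave = lg$wave[-n][keep], mode = lg$mode[-n][keep],
                   rr = 60 / dt[keep])
  aggregate(rr ~ wave + mode, df, mean)
}

# noiseless, artifact-free variant (breathing still on)
noiselessParams <- function(seed = 1, ...) {
  SimulationParams(seed = seed, noiseSigma = 0, artifactMagnitude = 0, ...)
}

extdataPath <- function(name) system.file("extdata", name, package = "maskflow")
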