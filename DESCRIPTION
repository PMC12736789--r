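Package: maskflow
Title: Breathing Detection and Moisture-Saturation Kinetics from Mask-Mounted
    Humidity Sensor Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of multichannel resistance recordings from printed
    humidity sensor arrays worn on filtering facepiece (KN95-type) masks
    during a scripted breathing protocol. Provides a seeded simulator of
    sensor-array recordings (exponential moisture-saturation baseline,
    breathing oscillation, overflow saturation, motion artifacts),
    preprocessing (overflow clipping, robust motion-outlier removal, phase
    segmentation, defective-sensor exclusion, array mean), breath-by-breath
    feature extraction (inter-breath interval, respiration rate, amplitude)
    with per-wave summaries and normal/deep classification, first-order
    sorption kinetic fitting of the saturation curve with a two-regime
    log-linear decomposition, and spatial airflow mapping (min-max humidity
    index, inverse-distance-weighted 2D fields, zone summaries) across the
    19-sensor-per-side mask layout. Recordings are stored as
    SummarizedExperiment objects (sensors by timepoints).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'synth.R'
    'preprocess.R'
    'breath.R'
    'kinetics.R'
    'spatial.R'
    'io.R'
    'maskflow-package.R'
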