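# maskflow

Breathing detection and moisture-saturation kinetics from mask-mounted
humidity sensor arrays.

A filtering facepiece (KN95-type) mask accumulates exhaled moisture while it
is worn, which affects breathability and filtration. Printed humidity
sensor arrays (19 sensors per mask side, resistance read out at 3 Hz by a
multiplexed logger) turn this into a measurable signal: the sensing film's
resistance falls as humidity rises, so each exhale is a resistance dip and
the slow saturation of the mask membrane is a decaying baseline. `maskflow`
is for researchers analysing such in-operando recordings — or prototyping
analyses without hardware, via its seeded simulator.

The core model is first-order sorption kinetics for the masked segment of a
scripted session:

    R(t) = a * exp(-b t) + c + r(t)

with `c` the equilibrium (saturation) resistance, `a = R0 - c` the
initial-minus-equilibrium amplitude, `b` the decay rate (inverse time
constant of moisture transport through the membrane), and `r(t)` the
breathing oscillation, which is treated as a structured residual rather
than fitted. On a log scale the same curve decomposes into an early
straight line `log(a) - b t` and a late saturation level `log(c)`, which
the package also estimates and uses to seed the nonlinear fit. Around the
fit sit the rest of the analysis chain: overflow clipping at 1e8 ohm,
Hampel-style motion-artifact removal, defective-channel exclusion, breath
detection with per-breath features (interval dt, RR = 60/dt, f = 1/dt,
amplitude Rmax - Rmin), per-wave normal/deep summaries, and spatial
humidity-index maps over the mask layout.

Recordings are `SummarizedExperiment` objects (sensors x timepoints) with
the layout in `rowData` and ambient/protocol metadata in `metadata`; all
user-facing functions are camelCase (`simulateRecording`, `fitExponential`,
`detectBreaths`, `summarizeWaves`, `makeFrames`, ...). See the methods
vignette (`vignettes/maskflow-methods.Rmd`) for the model, the generator
and every tunable parameter.

## Worked example

Simulate a default session (six waves of 4 min normal + 1 min deep
breathing between two unmasked 2 min segments), preprocess, fit the
kinetics and summarise the breathing:

```r
library(maskflow)

rec <- simulateRecording(SimulationParams(seed = 11))
rec
#> MaskRecording: 38 sensors x 6121 samples; 0.0-2040.0 s
#>   ambient: 22.8 degC / 53 % RH; overflow samples: 27398
#>   ProtocolSpec: 120 s pre | 6 x ( 240 s normal + 60 s deep ) | 120 s post; total 2040 s

recC  <- clipOverflow(rec)
seg   <- segmentPhases(recC)
am    <- arrayMean(recC, detectDefectiveSensors(recC))
clean <- removeMotionOutliers(am@time, am@values, labels = seg$labels)

fitExponential(clean@time, clean@values, window = seg$fitWindow)
#> ExpFitResult: R(t) = 7.669e+05 * exp(-0.002 t) + 1e+05   (R^2 = 1.0000)
#>   window 200-1920 s, breakpoint 1267.5 s, 5159 points
#>   log regimes: early 13.6052 -0.00143 t | late level 11.9151

ib <- seg$labels == "breathing"
events <- screenAnomalies(detectBreaths(clean@time[ib], clean@values[ib]))
summarizeWaves(events, ProtocolSpec())
#> SessionSummary over 6 waves
#>   W1: normal  18.0 bpm (n=66) | deep   7.9 bpm (n= 7)
#>   W2: normal  18.1 bpm (n=71) | deep   7.9 bpm (n= 7)
#>   ...
#>   mean RR difference (waves 2,3,4,5,6): 10.15 bpm
#>   mean amplitude difference: 172.9 ohm
```

Reading the numbers: the fit recovers the simulated decay — time constant
`1/b = 500 s`, saturation at `c = 1e5` ohm, and `a` referenced to the 200 s
window start (`9e5 * exp(-0.002 * 80) = 7.669e5`) — with an R² near 1. The
wave table recovers the simulated 18/8 breaths/min rates, and the session
delta of 10.15 bpm matches the simulated normal-minus-deep difference of
10. Wave 1 is reported but never enters the session means (the membrane is
still saturating there).

`runPipeline(runConfigDefaults(seed = 11))` chains all of the above plus
spatial frames into a `SessionReport` and, given an `output_dir`, writes
deterministic CSV tables (per-wave summaries, fit coefficients, zone
summaries, frames) and the resolved configuration.

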