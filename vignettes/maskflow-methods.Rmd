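---
title: "Breathing detection and moisture-saturation kinetics from mask-mounted humidity sensor arrays"
author: "maskflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{maskflow methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maskflow)
```

## The measurement and the problem

A filtering facepiece (KN95-type) mask accumulates moisture as its wearer
breathes, which degrades both comfort and filtration. `maskflow` analyses
recordings from printed humidity sensor arrays (19 sensors per mask side)
sewn onto such a mask and sampled by a multiplexed data logger at a nominal
3 Hz per channel. The sensing film's resistance *decreases* as humidity
*increases* (an inverse response), so each exhale produces a resistance dip
and the slow saturation of the mask membrane appears as a decaying
resistance baseline.

A session follows a scripted protocol (`ProtocolSpec`): 2 min of unmasked
recording (ambient baseline), then six "waves" of 4 min normal breathing
plus 1 min deep breathing (30 min masked), then 2 min unmasked again. While
the mask is off, the dry sensors sit near or beyond the logger's measurable
range, so those segments contain readings clipped at $10^8\,\Omega$ and
literal `overflow` tokens.

## The kinetic model

Moisture transport through the mask membrane is diffusion-limited. For a
membrane of finite thickness the concentration relaxes through a series of
exponentially decaying modes; after a short transient the slowest mode
dominates, so the array-mean resistance during mask wear is modelled as
first-order sorption kinetics:

$$R(t) = a\,e^{-b t} + c + r(t),$$

where $c$ is the equilibrium (saturation) resistance once the membrane has
equilibrated with exhaled-air humidity, $a = R_0 - c$ is the
initial-minus-equilibrium amplitude, $b$ (1/s) is the decay rate — the
inverse time constant of moisture transport — and $r(t)$ is the
breathing-driven oscillation. The oscillation is deliberately *excluded*
from the fitted model: `fitExponential()` fits $a e^{-bt} + c$ only, and
$r(t)$ remains a structured residual. Fit quality is summarised by
$R^2 = 1 - SS_{res}/SS_{tot}$ on the fit window.

On a log scale the curve splits into two straight regimes, which
`twoRegimeLogFit()` estimates directly: early, while $a e^{-bt} \gg c$,
$\log R \approx \log a - b t$ (natural logarithms; the slope estimates
$-b$); late, $\log R \approx \log c$, the saturation level. The two-regime
fit both provides an interpretable decomposition and seeds the nonlinear
optimiser.

Numerical choices:

* The fit window is 200–1920 s from recording start, inside the stable
  breathing period — it excludes the don/doff transients. The window is a
  configuration knob (`kinetics.window`).
* Optimisation uses bounded Levenberg–Marquardt (`minpack.lm::nlsLM`) with
  $a \in (0, 10\max R)$, $b \in (10^{-6}, 1)$ s$^{-1}$,
  $c \in (0, \max R)$; these keep the exponential identifiable on a
  ~1700 s window. Time is referenced to the window start, so the reported
  $a$ is the modelled resistance excess over $c$ at $t_{lo}$.
* The regime breakpoint, when not supplied, is found by extrapolating a
  provisional early line (first quarter of the window) until it comes
  within 0.05 log-units of a provisional late level (last quarter), then
  refitting both segments on that split. This mimics choosing the split
  visually on a log plot without a manual step.
* A constant series leaves $b$ unidentifiable; the fit then raises a classed
  error (`maskflowFitError`) carrying its starting values rather than
  returning a spurious result.

## Preprocessing

1. **Overflow clipping** (`clipOverflow`): `overflow` markers and values
   above $10^8\,\Omega$ are set to exactly $10^8$, reproducing how
   out-of-range unmasked segments are handled before analysis.
2. **Phase segmentation** (`segmentPhases`): samples are labelled
   pre/breathing/post from the protocol clock.
3. **Defective-sensor exclusion** (`detectDefectiveSensors`): channels
   saturated for most of the breathing phase, frozen (near-zero variance;
   connector strain can latch a reading), or showing non-physical values
   ($\le 0\,\Omega$) are excluded from the array mean, with reasons logged.
4. **Array mean** (`arrayMean`): per-timepoint arithmetic mean over the
   included channels; both mask sides are pooled by default.
5. **Motion-outlier removal** (`removeMotionOutliers`): a Hampel-style
   despiker. A sample is flagged when it deviates from a centred rolling
   median by more than $k = 5$ times a rolling MAD scale, and replaced by
   linear interpolation between its nearest unflagged neighbours
   (nearest-value fill at the ends). Don/doff motion artifacts — a few
   erratic samples when the mask is handled — are exactly this kind of
   spike. Two details matter:
   * Each protocol phase is cleaned *independently* (pass `labels`).
     Otherwise the $\sim 100\times$ level steps at don/doff count as
     deviations, and interpolation across a step drags unmasked-level
     values into the breathing segment.
   * The MAD scale is floored by the median absolute first difference of
     the series. On a strongly monotone stretch a rolling median returns
     (nearly) the centre sample itself, so the raw MAD can collapse to
     zero and legitimate samples would be flagged; the floor encodes the
     legitimate sample-to-sample excursion of trend plus breathing.

   The rolling window is 30 s: several breath periods even for slow deep
   breathing (so the oscillation is part of the background, not a spike),
   yet short against the ~500 s saturation timescale.

A related pitfall shaped the breath detector: detrending against a rolling
*median* fails on this data, because on a monotone decay the running median
equals the running signal and the detrended residual vanishes. All
detrending in the package therefore uses a centred rolling *mean* (with
shrinking windows at the edges), which follows the trend while averaging
the zero-mean oscillation away.

## Breath-by-breath features

`detectBreaths()` detrends the cleaned breathing-segment series (30 s
rolling mean), negates it so exhale resistance troughs become peaks, and
finds local maxima with a minimum spacing of 2 s (at most 30 breaths/min)
and a prominence threshold of 0.2 times a rolling inter-quartile range of
the detrended signal. Prominence-based peak selection is implemented in the
package (candidate maxima, valley-to-valley prominence, then greedy
min-distance filtering keeping higher peaks).

Each pair of consecutive peaks yields an inter-breath interval $\Delta t$,
from which the respiration rate $RR = 60/\Delta t$ (breaths/min), frequency
$f = 1/\Delta t$ (Hz), and amplitude $A = R_{max} - R_{min}$ of the
detrended signal between the peaks. `screenAnomalies()` automates the
manual review of implausibly short breaths: an interval $\le 1$ s is
treated as a spurious double detection and merged with its successor when
the merged interval is physiologically credible ($\le 15$ s), otherwise
flagged and excluded from aggregates.

`summarizeWaves()` assigns each breath to a wave and mode by the protocol
phase containing its starting peak, and averages RR and amplitude per
wave × mode. Two aggregation rules:

* **Wave 1 is never aggregated** — the membrane is still absorbing moisture
  there and the signal is not yet stationary around the decay.
* **Mode-boundary-straddling intervals are dropped.** A peak-to-peak
  interval measured between a normal breath and a deep breath characterises
  neither mode; with only ~7 deep intervals per 1 min wave, a single mixed
  interval can bias that wave's mean by around 1 breath/min, which no
  assignment rule repairs. Dropping them is the reproducible analogue of an
  analyst discarding transition breaths.

The session-level summary is the mean, over waves 2..n with both modes
available, of (normal mean RR − deep mean RR); waves with a missed cue are
skipped. `classifyBreathing()` labels a window deep when its mean RR falls
below 15 breaths/min — the midpoint between typical instructed deep rates
(~5–14) and the 12–20 breaths/min normal range — with ties going to normal.

## Spatial airflow mapping

For visualising airflow, each usable sensor is min–max normalised over the
stable breathing window, $X' = (X - X_{min})/(X_{max} - X_{min})$, and
complemented into a humidity index $1 - X'$: 1 is the wettest observed
state (resistance minimum, after exhale), 0 the driest (after inhale). The
normalisation window excludes the unmasked segments on purpose: their
near-overflow extremes would crush the breathing dynamics into a sliver of
the scale.

`makeFrames()` evaluates the index per sensor at requested timestamps and
interpolates it onto a grid inside a half-mask silhouette polygon by
inverse-distance weighting (power 2) — a scheme that needs no mesh
assumptions for 19 scattered points and never exceeds the range of the
contributing sensors. An optional quarter-ellipsoid shell
(`surfaceCoords`) maps the same field to 3D; video rendering is out of
scope, frames are data products. `assignBreathPhase()` labels samples
inhale/exhale from the sign of the central-difference derivative of the
detrended array mean (exhale = resistance falling), with a small deadband
near zero crossings; at 3 Hz the ±1-sample central difference already
averages over ~0.7 s, so no extra smoothing is applied by default — wider
smoothing mainly biases the flank turnarounds of the asymmetric breath
pulse.

Zone-level comparisons (`zoneSummaries`) are most informative at **deep
exhale peaks** (resistance troughs during deep waves). Because each sensor
is normalised by its own extrema, a sensor with a stronger breathing
response also has a wider personal scale; away from the troughs this
rescaling cancels — or even inverts — the between-zone contrast, whereas at
a deep trough the breathing excursion and the personal scale grow together
and the ordering by airflow exposure (mouth/nose > chin > cheek > nose
bridge) is preserved.

## The synthetic-data generator

No public recordings exist for this kind of session, so `simulateRecording`
generates them with the statistical structure the analysis assumes:

* the shared saturation baseline $a e^{-b(t - t_{don})} + c$ during mask
  wear, with defaults $a = 9\times10^5\,\Omega$, $b = 2\times10^{-3}$
  s$^{-1}$, $c = 10^5\,\Omega$ — a ~500 s time constant inside a
  $10^5$–$10^8\,\Omega$ range, plausible for mid-humidity days;
* a breathing oscillation built from smooth asymmetric raised-cosine
  breath pulses (fast exhale fall over 35% of the breath, slower inhale
  recovery). Each pulse is exactly zero-mean and zero-median over its
  breath, so detrending assumptions hold by construction. Peak-to-trough
  amplitudes default to 140 Ω (normal) and 480 Ω (deep) at the mouth zone,
  which under the default layout gives array-mean amplitudes of roughly
  70 and 240 Ω;
* instructed rates of 18 (normal) and 8 (deep) breaths/min with lognormal
  inter-breath jitter (5% fractional s.d.). Breath onsets are
  phase-aligned: a new breath starts at every mode-boundary cue, with the
  preceding interval truncated (or, below half a period, the previous
  breath extended) to end exactly at the boundary — the natural reading of
  a scripted protocol, and it makes the generator's truth log usable as a
  per-wave oracle;
* zone gains on the oscillation (mouth/nose 1.0, chin 0.5, cheek 0.3,
  nose bridge 0.1), encoding the qualitative airflow ordering on a
  well-fitted mask;
* unmasked segments at a dry level of $5\times10^8\,\Omega$, recorded as
  `Inf` overflow markers past the $10^8$ logger limit (clipping happens in
  preprocessing, as with real exports);
* two-sided multiplicative spike artifacts (×4 and ÷4 alternating for
  1.5 s, i.e. 4–5 samples) at don and doff;
* additive Gaussian noise (20 Ω per channel) and a common 3 Hz clock for
  all channels — breath periods (≥3 s) dwarf the multiplexer scan time, so
  channel skew is neglected.

Everything is drawn from a locally seeded RNG: the same seed reproduces a
recording bit for bit, and the caller's RNG state is untouched. The
recording object (`MaskRecording`, a `SummarizedExperiment` with sensors as
rows) carries the generator's breath schedule and parameters in its
metadata, which the test suite uses as ground truth.

What the generator does **not** emulate: participant-specific baseline
shapes beyond $(a, b, c)$, day-to-day membrane memory, ambient-humidity
drift within a session, sensor-to-sensor calibration differences, slow
connector degradation, or zone-dependent saturation dynamics (all sensors
share one baseline, as the kinetic model assumes). Tests passing on this
generator therefore demonstrate that the pipeline recovers what it assumes;
they do not certify performance on real recordings with unmodelled
structure. In particular the simulated $R^2$ of the kinetic fit is
essentially 1, because the modelled residuals (oscillation plus noise) are
small against the decay range — observed fit qualities on real sessions sit
lower.

## Problem sizes and reproducibility

The test suite and the acceptance script run the full pipeline (38 channels
× 6121 samples) across 20 seeds for the fit-quality and
parameter-recovery studies, and single seeded sessions elsewhere; a full
pipeline run takes a few seconds. All pipeline outputs are deterministic
given the configuration and seed; the run directory contains the resolved
configuration, and machine-readable tables reproduce byte for byte.

## Known limitations

* The automated merge rule for sub-second breaths is a reproducible
  stand-in for manual review; pathological double peaks further than 15 s
  from a neighbour are dropped rather than repaired.
* The breakpoint heuristic of the two-regime fit assumes the window
  actually contains both regimes; on a window ending long before
  saturation the "late level" is still decaying and overestimates
  $\log c$ (the nonlinear fit does not share this bias).
* Zone orderings are evaluated at deep exhale peaks for the reason above;
  mid-flank frames are still generated but carry little between-zone
  contrast under per-sensor normalisation.
* With protocols much shorter than the default, the 200–1920 s fit window
  must be re-specified to fit inside the breathing phase.
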