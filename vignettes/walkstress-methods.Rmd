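---
title: "Methods: capturing location-based pedestrian distress from wearable biosignals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: capturing location-based pedestrian distress from wearable biosignals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Pedestrians exposed to negative environmental stimuli — broken sidewalks,
litter, unattended dogs, missing crosswalks — show short-lived physiological
reactions: bursts of skin conductance responses (SCRs), gait slowdowns, and
heart-rate elevations. If many people react at the same place, those reactions
can be pooled spatially into a *collective distress* signal for each stretch of
street, and a classifier can be asked whether a street segment contains a
reported stimulus using only the pooled biosignal aggregates.

`walkstress` implements that pipeline end to end for wrist-worn
electrodermal activity (EDA, 4 Hz), blood volume pulse (BVP, 64 Hz),
waist-worn triaxial accelerometry (50 Hz) and GPS (one fix per 3 s), plus
per-trip self-reports of stimulus locations drawn from a canonical list of
14 types. Because no public dataset exists with this combination of streams,
the package ships a synthetic study generator with known ground truth; every
stage of the pipeline is exercised and tested against it.

# Preprocessing

**EDA.** The raw signal is smoothed by FIR convolution with a 12-sample
unit-sum Bateman kernel, `h[k] = exp(-k/(tau1 r)) - exp(-k/(tau2 r))` with the
conventional constants tau1 = 2 s, tau2 = 0.75 s at r = 4 Hz. The smoother is
causal (reflect padding at the start only): an SCR cannot precede its driver,
and a causal kernel keeps onsets in place while the unit sum preserves signal
level. Trips are screened out when (1) mean EDA falls below 0.01 µS, (2) no
SCR is detected, or (3) SCR frequency exceeds 25 counts *per minute*. The
published rule does not name the denominator of rule (3); we use counts per
minute because a per-trip total would make the screen depend on trip length.
The visual-inspection step of the original procedure is replaced by these
deterministic rules (a human-in-the-loop step cannot be tested); plots can be
exported for manual review.

**SCR detection.** Tonic skin conductance level (SCL) is a 4-s rolling median;
the phasic residual drives trough-to-peak detection. Event amplitude is
measured on the smoothed EDA (peak minus preceding trough, searching the
trough as the last near-minimal sample so flat baselines give the rise onset);
events below 0.01 µS (a common convention) are dropped. The rolling-median
window and minimum amplitude are configurable.

**IMU.** Each axis passes a 4th-order Butterworth low-pass at 4 Hz, applied
zero-phase so event times are not shifted. Walking interruptions are flagged
from the acceleration magnitude via a short-time Fourier transform (3-s Hann
window, 50% overlap): frames whose peak spectral amplitude in the 0.5–3 Hz
gait band stays below 0.5 (in units of g; the spectrum is scaled so a sinusoid
of amplitude A reads A) for at least 15 s become non-walking intervals;
neighbours closer than one hop merge. The gait band and the overlap are
choices of this package — the published rule fixes only the window length,
the 0.5 amplitude and the 15 s minimum — and both are exposed in the
configuration, as is the assumption that input is in g.

**BVP.** Motion-artifact suppression uses a 5-level db4 discrete wavelet
transform with the universal soft threshold (noise scale from the finest
level's MAD) *plus* a robust cap that clips detail coefficients beyond 3x
their level's MAD-scale. Soft thresholding removes broadband noise but merely
shrinks large sparse burst coefficients, so the cap is the component that
actually suppresses artifacts. The wavelet stage runs **before** the
band-pass, although the published description lists the band-pass first:
once a 0.3-s burst has been band-limited to the cardiac band it is
indistinguishable from beats at every wavelet scale, and in our benchmarks
the band-pass-first order failed to reduce beat-count errors at all while the
wavelet-first order reduced them on every test trip. The band-pass itself is
a zero-phase Butterworth passing 0.6–4 Hz (36–240 bpm); the published
"0.4–0.6 Hz and 4–8 Hz cutoff" is read as the transition edges of that band,
the only reading under which the band contains plausible heart rates.

**Heart rate.** Systolic peaks with a 0.27-s refractory period (220 bpm),
instantaneous 60/IBI at beat midpoints, beats outside 30–220 bpm dropped, and
a centered 5-beat moving average (width configurable; the source describes
only "a moving average filter").

# Features

Six feature families feed the spatial stage: SCL, EDA PSC, stride time,
IMU PSC, mean heart rate and BVP PSC; SCR amplitude and SCR frequency are
additionally available to the window statistics. Stride time is the interval
between alternate heel-strike peaks on the largest-variance (vertical) axis —
two steps of the same foot — emitted at stride midpoints and never across an
interruption.

**Bottom-up segmentation.** Each representative series is segmented by the
classical bottom-up merge: start from two-sample segments and repeatedly merge
the adjacent pair with the smallest increase in total squared error until the
cheapest merge exceeds a cost cap (default `2 * var(series)`). A cap rather
than a fixed segment count keeps segment lengths data-driven; `Inf` merges to
a single segment.

**Physiological saliency cue (PSC).** With segment attributes `a_i` (segment
means) and centers `c_i`, `PSC(i) = sum_{j != i} w_ij |a_i - a_j|` where
`w_ij` normalizes inverse center distances `1/|c_i - c_j|`. The method's
sources name the idea — contrast of a segment against its neighbours — but
not a formula; this distance-weighted absolute contrast follows the saliency
lineage, is nonnegative, zero for a single segment, and symmetric for
mirror-symmetric inputs. An unweighted variant is available
(`weighting = "uniform"`). PSC is computed on the representative series of
each modality (1-Hz EDA, the stride-time series, the heart-rate series) so
that segment attributes are comparable within a family; computing IMU or BVP
saliency on raw 50/64-Hz samples would mix units and sampling rates.

All series are geocoded by linear interpolation of the GPS track and the
whole pipeline works in a planar metric CRS (WGS84 inputs are projected once
at load with a local tangent-plane projection), since every spatial constant
(40-m buffer, 1–150 m lengths) is metric.

# Stimulus-anchored window statistics

For each self-report, the passage time `t0` is the time of the GPS fix
nearest the reported location (the original interface slides along a time
bar but never formalizes this mapping; reports farther than 40 m from the
track are excluded). A *nonstimuli* window `[t0 - L, t0)` and a *stimuli*
window `[t0, t0 + L)` give paired feature means, with L swept from 5 to
240 s in 1-s steps. The post-passage placement of the stimuli window follows
the reactivity evidence that responses appear 5–10 s after passing a
stimulus. Pairs are excluded when a window leaves the trip span, when less
than 50% of a window survives interruption removal (a determinism-preserving
rule this package adds), or when a window overlaps the stimuli window of an
earlier retained report — earlier by `t0`, so the retained set does not
depend on input order.

Each feature and length is tested with the random-intercept model
`y_ij = mu + beta x_ij + u_i + e_ij` (subject random intercept, REML via
lme4, Wald z p-value; a singular fit falls back to pooled regression with a
flag), and per stimulus type with Welch's two-sample t-test at alpha = 0.05.
Welch is used because only "two-sample t-test" is specified and equal
variances are not defensible across window pairs. Raw p-values are reported
without multiple-testing correction, matching the original analysis; the
full grid is persisted and the smallest significant L per feature is
summarized (the original tables report one length per feature without
stating the selection rule; minimum-significant is the reading implemented).

# Spatial classification

Street centerlines are cut into POI segments of a target length (grid
1, 5, 10, 20, ..., 150 m) with a 40-m flat-capped buffer; a remainder span
at least half the target length stays its own segment, otherwise it merges
into the previous one (street ends are not discussed in the source). Each
geocoded feature point joins the segment whose centerline is nearest among
the buffers containing it, with exact ties to the lower segment id. Feature
values are z-normalized per trip and feature before pooling — supported by
the original heat-map figure showing per-trip normalized SCL — so the
classifier cannot exploit between-subject baselines; the switch is
configurable. Per segment and family, the mean and SD across all points of
all trips form 12 aggregate columns. A segment containing at least one
report is labeled *stimuli*, else *nonstimuli*.

Gaussian naive Bayes (features are continuous aggregates) is evaluated with
stratified fivefold cross-validation at segment level under a fixed seed;
missing aggregates are imputed with training-fold means, and no resampling
or reweighting addresses class imbalance — the unweighted average recall
(UAR, mean of per-class recalls, chance 0.5) is the imbalance-robust metric.
Folds are over segments (locations): once a segment pools many subjects'
trips, subject-grouped folds have no well-defined meaning at this level, so
that variant is not offered.

# The synthetic study generator

`synth_config()` defines the study conditions; `effect_scale` switches
between the strong-effect benchmark and its matched null.

| parameter | default | meaning |
|---|---|---|
| subjects / trips | 30, 5–10 | benchmark scale (the field study had 67 subjects, 3–76 trips, mean 23.3; desk-scale tests use fewer) |
| network | 60 streets x 100 m grid | surrogate street centerlines |
| walk speed / step rate | 1.4 m/s, 2 Hz | typical adult walking |
| background SCRs | 4 per min, ~0.3 µS | passes the quality screen (> 0, < 25 per min) |
| stimulus effects | 3 SCR burst of 0.5 µS, 20% stride slowdown, +8 bpm | injected for 30 s starting 5 s after passage |
| stimulus density | 5 per km | ~20% stimuli segments at 40 m, a workable minority share |
| report error | sigma = 5 m | reported locations deviate from true stimulus positions |
| GPS noise, pauses | 1 m; ~0.3 pauses of 20–40 s per trip | realistic nuisance structure |

Signals are generated from simple structural models: EDA as a drifting tonic
level plus Bateman-shaped SCRs (peak-normalized, tau 2 / 0.75 s); gait as a
phase-integrated sinusoid with harmonics on the gravity-offset vertical axis
(amplitude 0.8 g, in the range of brisk walking measured at the waist, and
comfortably above the 0.5 g interruption threshold); BVP as one raised-cosine
systolic bump per beat with a controllable instantaneous rate, optional
uniform-noise artifact bursts of 0.3 s. What the generator does **not**
emulate: real sudomotor or cardiovascular dynamics, electrode drift and
detachment, GPS multipath, terrain, weather, or subject-specific reactivity
differences. Passing tests on this benchmark therefore demonstrate that the
pipeline recovers effects *of the assumed structure* at realistic magnitudes
and noise levels — not field performance on real data, whose headline
accuracies are not reproducible without the original (undeposited) dataset.

Everything is driven by one integer seed; per-trip substreams are derived
deterministically so studies are bit-reproducible.

# Numerical choices and edge cases

- Half-open `[a, b)` windows and intervals everywhere; times are seconds
  since trip start after alignment; alignment trims to the common channel
  overlap, keeps the GPS fix just before time zero (a fix covers its 3-s
  interval), flags overlaps under 60 s unusable, and is idempotent.
- Bottom-up merges break cost ties at the earliest pair; the clean-step
  boundary test confirms agreement with the exhaustive optimum.
- Constant series z-normalize to zero; zero-variance aggregate columns are
  dropped before the naive Bayes fit (degenerate Gaussians).
- Beat detection needs at least 3 beats, otherwise an empty series with a
  warning; flat signals short-circuit.
- The classifier requires two samples per class and shrinks the fold count
  (with a warning) when a class is rarer than the fold count.

# Benchmark problem sizes

The test-suite and the acceptance script use: the default benchmark
(30 subjects, 5–10 trips) for end-to-end classification at 40 m; ten reduced
studies (10 subjects, 3–5 trips, 20 streets) for the segment-length trend;
500 simulated null fits and 50 effect-recovery replicates (30 subjects x 20
pairs) for LME calibration; 200 random series for the PSC oracle and 100
clean steps for the segmentation oracle. These sizes were chosen so the full
run completes comfortably on a laptop while keeping Monte-Carlo error well
inside the asserted margins.

# Known limitations

- The PSC formula and the bottom-up stopping rule live in prior work the
  source only cites; both are flagged, configurable, and validated here only
  against their own stated properties.
- The LME p-value is a Wald z-test; at very small subject counts it is
  anticonservative (the calibration benchmark uses 30 subjects).
- Segment buffers are flat-capped, so points beyond a street's end belong to
  no segment even within 40 m; intersection points go to the nearest street.
- The generator's stimulus effects are free parameters, not calibrated to any
  field dataset; only qualitative conclusions (signal recovery, multimodal
  gain, trend directions) transfer.
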