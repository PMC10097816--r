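# walkstress

Location-based collective pedestrian distress from geocoded wearable
biosignals.

When pedestrians pass negative environmental stimuli — broken walking
surfaces, blocked sidewalks, litter, unattended dogs, missing crosswalks
(14 canonical types) — their physiology reacts briefly: extra skin
conductance responses, longer strides, a small heart-rate bump.
`walkstress` turns raw wearable streams (EDA at 4 Hz, blood volume pulse at
64 Hz, triaxial waist accelerometry at 50 Hz, GPS at one fix per 3 s) plus
per-trip self-reports into a street-segment-level answer to the question:
*does this stretch of street contain a reported stimulus?* It is intended
for researchers in environmental health, walkability assessment and
ambulatory psychophysiology.

The pipeline:

1. **Preprocessing** — 12-sample Bateman smoothing of EDA with the published
   three-rule quality screen (mean < 0.01 µS, zero SCRs, > 25 SCR/min);
   zero-phase Butterworth filtering of IMU (4 Hz) with STFT-based walking
   interruption removal (3-s window, 0.5 g gait-band threshold, 15-s
   minimum); wavelet (db4) motion-artifact suppression and cardiac
   band-pass (0.6–4 Hz) of BVP; heart rate from systolic peaks with a
   5-beat moving average.
2. **Features** — SCL, SCR amplitude/frequency, stride time, mean heart
   rate, and per-modality *physiological saliency cues* (PSC): after
   bottom-up segmentation of a series into variable-length segments with
   means `a_i` and centers `c_i`, `PSC(i) = Σ_{j≠i} w_ij |a_i − a_j|` with
   inverse-distance weights `w_ij ∝ 1/|c_i − c_j|`. All features are
   geocoded along the GPS track.
3. **Stimulus-anchored statistics** — matched window pairs `[t0 − L, t0)` /
   `[t0, t0 + L)` around each report's passage time, swept L = 5…240 s;
   the random-intercept model `y_ij = μ + β x_ij + u_i + e_ij` per feature
   and Welch t-tests per stimulus type.
4. **Spatial classification** — street centerlines cut into POI segments
   (1–150 m sweep) with 40-m buffers; per-trip z-normalized features pooled
   to per-segment mean/SD; Gaussian naive Bayes under stratified fivefold
   cross-validation, scored by unweighted average recall
   (UAR = mean of per-class recalls; chance is 0.5 at any class imbalance).

Because no raw dataset of this kind is publicly deposited, the package ships
a deterministic synthetic study generator (`synth_config()`,
`simulate_study()`) with full ground truth — Bateman-shaped SCRs, pulsatile
BVP with controllable rate and artifacts, quasi-periodic gait with pauses,
GPS along a street grid, stimulus effects of configurable magnitude and
report-location error — so every stage is testable end to end.

## Worked example

```r
library(walkstress)

cfg <- synth_config(seed = 42, n_subjects = 6, trips_per_subject = c(3, 5),
                    network = list(n_streets = 20, street_length_m = 100))
study <- simulate_study(cfg)
study
#> <synth_study: 6 subjects, 20 trips, 32 reports, 10 stimuli, 20 streets (seed 42)>

proc <- process_trips(study$trips)          # preprocess + featurize all trips

sw <- sweep_segment_lengths(proc$features, study$reports, study$streets,
                            lengths_m = c(20, 40, 80), seed = 1)
sw[sw$feature_set == "all",
   c("segment_length_m", "share_stimuli", "uar",
     "recall_stimuli", "recall_nonstimuli")]
#>   segment_length_m share_stimuli   uar recall_stimuli recall_nonstimuli
#> 1               20         0.144 0.636          0.5               0.771
#> 2               40         0.220 0.776          0.769             0.783
#> 3               80         0.4   0.896          0.875             0.917
```

Reading the output: at 40-m segments, 22% of street segments contain at
least one self-report; the six-family naive Bayes recovers 77% of those
stimuli segments and 78% of the nonstimuli segments (UAR 0.78), and
stimuli-class recall grows with segment length — coarser segments pool more
trips per decision. `autoplot(sw)` draws the recall/UAR-versus-length view.

The window statistics work the same way:

```r
pairs <- extract_window_pairs(proc, study$reports, L_s = 30)
fit <- fit_lme(walkstress:::pairs_to_long(pairs, "scr_frequency"),
               feature = "scr_frequency", window_length_s = 30)
fit
#> <lme scr_frequency @ L=30 s: beta=0.8776 (se 0.505), p=0.0823,
#>  n=38 obs / 6 subjects, pooled fallback>
```

i.e. SCR frequency runs ~0.9 counts/min higher in the 30 s after passing a
reported stimulus than in the 30 s before, on this small demo study (38
retained pairs; the fixed seed's between-subject variance is ~0, hence the
flagged pooled fallback). `tidy()` and `glance()` return these fits as
tibbles; `sweep_window_lengths()` runs the full 5–240-s grid.

A configuration-driven run of all five stages (simulate → preprocess →
features → stats → spatial) with an output manifest:

```r
run_pipeline(validate_config(list(seed = 11)), out_dir = "run1")
```

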