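---
title: "Extracting time-to-fixate from driving-simulator hazard scenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting time-to-fixate from driving-simulator hazard scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hazgaze)
```

## The measurement problem

Hazard-perception testing in a driving simulator asks how quickly a driver
*notices* a suddenly appearing pedestrian, separately from how quickly they
*react* with the pedals. The quantity of interest is the **time to fixate
(TTF)**: the interval from the hazard's first appearance in the scene-camera
video (t1) to the first gaze sample that lands inside the hazard's bounding
rectangle (t2), so TTF = t2 − t1. The companion **perception response time
(PRT)** runs from a stimulus (a stop sign) to the brake pedal crossing a
force threshold, and therefore contains TTF plus central processing and
movement time.

hazgaze automates the whole chain from three time-aligned tabular streams —
per-frame object detections of the pedestrian (e.g. from a YOLO-class
detector, consumed behind a CSV adapter contract; the detector itself is out
of scope), gaze coordinates in scene-camera pixels, and the simulator log —
to a per-subject feature record, and then runs the group-comparison
statistics used to contrast fitness-to-drive groups (fit, conditionally fit,
unfit).

## The event model

All streams share one clock in milliseconds from recording start. Video
frames are half-open intervals `[i/fps, (i+1)/fps)`, so each timestamp maps
to exactly one frame (`time_to_frame()`); the default geometry is a
960 × 540 scene camera with video and gaze both at 50 Hz, configurable for
other hardware.

The per-session chain (`run_pipeline()`, or `compute_ttf()` for the gaze
events alone):

1. **Manual corrections** (`apply_corrections()`) are replayed over the raw
   detection table in file order (`replace` / `add` / `delete`); detector
   output on small, partly occluded pedestrians routinely needs such fixes.
   Corrections are applied before onset determination.
2. **Track assembly** (`build_tracks()`) keeps person-class detections at or
   above the confidence floor (default 0.25, the usual detector default).
   Supplied track ids are trusted; otherwise consecutive-frame detections
   are greedily linked at IoU ≥ 0.3.
3. **Gap interpolation** (`interpolate_boxes()`) bridges detector dropouts
   of up to 5 frames by per-coordinate linear interpolation; longer gaps
   stay open.
4. **Hazard onset t1** (`hazard_onset()`) is the start time of the earliest
   tracked frame inside the analysis window. The window is an explicit
   `scene_segment()` when the scene cut is known, otherwise the span of the
   hazard tracks; we deliberately replaced content-based scene recognition
   with this explicit window. When two pedestrians enter on the same frame,
   t1 is the frame time, not track-specific.
5. **First gaze on target t2** (`first_gaze_on_target()`) scans valid gaze
   samples from t1 to the segment end and stops at the first one inside
   *any* hazard box of the sample's frame (the scene has two children and
   no principled way to prefer one, so the union of person boxes ends the
   search). The hit test is a closed rectangle: a gaze point exactly on the
   edge counts as inside, the conservative reading of "falls within the
   detection frame". A single sample suffices — t2 is a raw gaze-in-ROI
   event, not a dwell-filtered fixation, so no I-VT/I-DT classification is
   applied. Invalid samples cannot certify a fixation and are skipped.

Event flags are mutually exclusive: `anticipatory` (gaze already on the
hazard at onset, TTF = 0 — excluded downstream since nothing was "noticed"),
`sub_saccade` (0 < TTF < 120 ms, faster than the ISO 15007 saccade duration;
flagged but *kept*), `miss` (gaze never reaches the hazard in the segment),
`no_onset` (no qualifying detection).

## Companion features

* **IGD** (`initial_gaze_distance()`): Euclidean pixel distance from the
  gaze point at onset to the hazard-box centre, rounded to the nearest
  integer pixel *before* conversion to visual degrees. The angle factor
  defaults to `horizontal_fov_deg / width_px` (82° / 960 px ≈ 0.085°/px, a
  documented scene-camera geometry class) and must be overridden when the
  device manual provides a calibrated factor. Whether "initial gaze" means
  the sample at t1 or the nearest valid one is not fixed by the definition;
  we take the nearest valid sample within ±100 ms and flag its absence.
* **Speed at onset** (`speed_at_onset()`): the nearest simulator-log sample
  (ties to the earlier one); logs are dense relative to speed dynamics, so
  interpolation would add nothing.
* **TTC** (`time_to_collision()`): ego-to-pedestrian distance divided by
  ego speed, `d / (v/3.6)` seconds.
* **PRT** (`perception_response_time()`, `brake_response_times()`,
  `average_prt()`): per stop-sign trigger, the first log sample *strictly
  after* the trigger with brake force ≥ 75 N; a pedal already pressed at
  trigger time is not a response, and each search window ends at the next
  trigger so one braking event cannot satisfy two stop signs. Repetitions
  outside 0.5–4 s (anticipations and misses) are discarded before
  averaging; one or two missing repetitions still yield a subject mean.
* **Type-B timing uncertainty** (`type_b_uncertainty()`): an event
  timestamp quantised at resolution r carries standard uncertainty
  `r / (2√3)` under a uniform error distribution — 5.77 ms at the 20 ms
  frame period, negligible against between-subject TTF spread.

## Screening and quality control

Session-level QC (`qc_session()`) reproduces the exclusion taxonomy:
frozen gaze (zero coordinate variance across the segment), missing data
(invalid fraction above 0.5), recording pauses (an inter-sample gap above 3
nominal periods), plus the anticipatory/no-onset/miss event flags. The 0.5
and 3-period thresholds are our own defaults for what the original workflow
judged by manual inspection; both are config-exposed and reported with the
measured quantity.

Cohort-level screening (`screen_ttf()`, `screen_prt()`) applies two rules in
a single pass over the original cohort: TTFs at or above 500 ms are
invalid (a glance that slow is a miss), and TTFs more than three
interquartile ranges above the third quartile are outliers (one-sided,
pooled across groups, type-7 linear-interpolation quantiles). The removal
set is the union of both flags, which makes the result independent of rule
order. Averaged PRTs get the same one-sided IQR rule after the
per-repetition range filter.

## Group statistics

`hazard_stats()` assembles the full report: per-group summaries (SD with
Bessel's correction), Welch's heteroscedastic ANOVA for TTF (TTF is not
normal and group variances differ), Tukey HSD with 0.95 simultaneous
confidence (Tukey–Kramer for unequal n), a sequential-SS (Type I) general
linear model `ttf ~ fitness + speed + igd + ttc + fitness:igd:ttc` with a
rigor α of 0.001, Shapiro–Wilk on its residuals, and Pearson correlations
of TTF with each covariate. Two deliberate fidelity choices: classical
pooled-variance Tukey HSD is paired with Welch's ANOVA exactly as in the
published analysis (not "corrected" to Games–Howell), and since the exact
GLM formula was not printed, we fix the named main effects plus the single
reported three-way interaction, entered in the listed order with sequential
sums of squares. PRT analyses are restricted to subjects with a TTF, and a
classical one-way F test for PRT is reported alongside Welch's because
averaged PRTs conform to normality. An `include_outliers` switch re-runs
everything with flagged TTFs kept, the standard robustness check.

Tukey adjusted p-values are computed by direct numerical integration of the
studentized-range upper tail (relative tolerance 1e-11): the stock `ptukey`
carries ~1e-8 absolute error, visible when checking the exact k = 2
identity p_adj = pooled-t p. Confidence intervals use the standard
`qtukey`-based half-width and are symmetric about the observed difference
up to floating-point rounding.

## What the generators emulate — and what they do not

`generate_session()` builds a session with known ground truth: a linear
pedestrian trajectory entering at a configured frame, a gaze trace that
holds a road fixation and steps onto the box centre after the configured
latency (plus Gaussian noise, optional linear slippage drift of the
horizontal coordinate, and optional invalid samples), and a simulator log
whose brake force is a step function at trigger + delay. Defaults are the
study conditions: 50 Hz streams, onset 3 s into an 8 s segment, ~240 ms
latency, 20 km/h, three stop-sign repetitions. The gaze model is
deliberately a fixation-to-step switch with no saccade kinematics: t2 is a
gaze-in-box event, so main-sequence realism would add nothing the pipeline
can detect. Consequences: recovery tests show the event logic is correct to
one gaze period, but they cannot certify behaviour under smooth pursuit,
blinks mid-saccade, or real slippage dynamics. `random_session()` is the
adversarial counterpart (uniform gaze, random walks, dropouts, off-class
tracks) used to cross-check `compute_ttf()` against a brute-force scan of
every gaze-sample × box pair.

`generate_cohort()` draws per-subject features matching the published
group summaries: group sizes (20, 17, 19), truncated-normal TTFs inside
[100, 500) ms and PRTs inside [500, 4000] ms — truncation at the validity
bounds guarantees generated cohorts survive the screens except for
deliberately injected outliers — and lognormal speed/IGD/TTC (their
reported ranges are clearly right-skewed; the lognormal is a pragmatic
choice, config-only and not asserted against any published value).

## Numerical conventions and problem sizes

Half-open intervals everywhere (frames, segments) so boundary samples are
assigned exactly once; closed-rectangle hit tests; ties in nearest-sample
lookups resolve to the earlier sample; quantile type 7. The test suite
checks the event chain against an independent brute-force implementation on
1000 random sessions, ground-truth recovery on 200 clean sessions (median
TTF error ≤ one 20 ms gaze period; brake delays recovered exactly for step
profiles), the statistical identities (Welch F(k=2) = t², Tukey
p_adj(k=2) = pooled-t p at 1e-10), and the separation pattern on 100
simulated cohorts (fit vs either impaired group significant at 0.01 in well
over 80% of replicates; conditionally-fit vs unfit rarely separated) —
sizes chosen to exercise every code path at desk scale.

## Known limitations

* Onset is defined by the detector (plus corrections): a late-detecting
  model biases t1 late and TTF short; the correction layer, not the
  pipeline, must fix that.
* No automated detection of physical setup faults (tilted or repositioned
  glasses) and no slippage *correction* — slippage is only simulated to
  probe robustness.
* Full numeric reproduction of the published group tables requires the
  study's released per-subject parameter table, which is distributed
  separately and not bundled; with it, `hazard_stats()` on the features
  dialect reproduces the printed statistics (see the acceptance test).
* The optional video-rendering exercise of the detector-adapter contract is
  not included; the adapter is specified at the CSV level.
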