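---
title: "Methods: skeleton fitting, honest step extrema, and agreement statistics"
author: "gaitmetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: skeleton fitting, honest step extrema, and agreement statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitmetrics)
```

# Overview

`gaitmetrics` implements the analysis back end of a monocular (smartphone)
video gait assessment: given per-frame 2D keypoints in pixel space and 3D
keypoints in meters — the typical output of neural pose detectors — it
produces the four spatiotemporal gait parameters that pressure-sensitive
walkways report (gait speed in m/s, cadence in steps/min, step length in cm,
step time in s), plus auxiliary kinematics, and the method-agreement
statistics used to validate such a system against a walkway.

The neural detectors themselves are out of scope. In their place the package
ships a parametric kinematic walking simulator that produces ground-truthed
pose sequences with controllable estimation noise, so that every stage of
the pipeline — and the pipeline end to end — is testable at desk scale.

The processing chain is:

1. `generate_walk()` / `read_pose_sequence()` — obtain a `pose_sequence`;
2. `optimize_sequence()` — fit an anatomically consistent, temporally
   smooth 3D skeleton and recover per-frame camera distance;
3. `foot_distance_signal()` → `smooth_signal()` → `extrema_candidates()` →
   `honest_extrema()` → `segment_steps()` — detect steps;
4. `step_metrics()` / `summarize_gait()` (or `analyze_gait()` for the whole
   sub-chain) — per-step metrics and trial averages;
5. `icc()`, `mean_diff_ci()`, `bland_altman()`, `validity_report()`,
   `run_study()` — method agreement against a reference system.

# Data model

A `pose_sequence` holds dense arrays of 2D (`u`,`v` pixels, v growing
downward) and/or 3D (`x` lateral, `y` vertical-up, `z` depth, meters)
keypoints for a fixed 21-joint skeleton (head top, head, neck, chest,
pelvis, and left/right shoulder, elbow, wrist, hip, knee, ankle, heel,
toe), connected by 20 bones forming a tree rooted at the pelvis. Detector
outputs with other naming conventions are mapped through an alias table.
Frames are implicitly timestamped at `i / fps`. Missing joints are `NA` and
allowed in 2D (occlusion); the optimizer requires the pelvis, neck, hips,
knees and ankles in every 3D frame and interpolates joints that are missing
only sporadically.

Bone lengths for a subject of known stature come from a proportion table
(`anthropometry.json`, editable): each bone is a fixed fraction of height,
with classical segment values (thigh 0.245 h, shank 0.246 h, ...). The
vertical ankle-to-head-top chain sums to 0.961 h, the remainder being the
standing ankle height. The table is deliberately a data file: it pins the
tests and lets users substitute population-specific tables.

# The skeleton optimizer

## Energy

The fitter minimizes a four-term energy over the 3D joint positions of the
whole sequence, subject to *hard* bone-length constraints derived from the
subject's height:

* **Inverse-kinematics term** (m²): each 2D keypoint is back-lifted along
  its pixel ray to a metric 3D point, and the term is the weighted mean
  squared distance between the candidate and these lifted points. In
  `energy_components()` the lift uses the candidate's own depth (the term
  then measures transverse-to-ray inconsistency and vanishes for a
  self-consistent sequence); during descent the lift depth is frozen at the
  initialization, which turns the lifted points into fixed data anchors —
  including a depth residual that pins each joint's depth (see
  *Why depth is treated asymmetrically* below).
* **Projection term** (squared angular error): pinhole reprojection error
  between the candidate and the 2D keypoints, normalized by the focal
  length so its scale is comparable to the metric terms at typical
  distances.
* **Smoothness term** (m²): a hinge on per-joint frame-to-frame
  displacement beyond a velocity allowance (`smooth_allow`, default 8 m/s —
  above the peak swing-foot speed of fast walking, ~7 m/s), so genuine
  motion is free and only jitter beyond physiologic speeds is penalized.
* **Depth term** (m²): the same hinge construction on the frame-to-frame
  change of the root (pelvis) depth beyond `depth_allow` (default 4 m/s,
  above the peak pelvis depth rate of a fast frontal walk).

Default weights are `(1, 1, 0.5, 0.5)`. The hinge construction makes a
clean, self-consistent walk an exact zero-energy fixed point of the
optimizer — a property the test suite asserts — which squared
first-difference penalties could not provide (a walker approaching the
camera has nonzero depth rate in every frame).

## Descent

Optimization is projected gradient descent with backtracking: a gradient
step, then re-imposition of the exact bone lengths by a forward-kinematics
pass from the pelvis (each child joint re-placed along its current
direction at the target length), accepting the step only if the total
energy decreased. The recorded energy trace is therefore non-increasing by
construction. Convergence: relative energy change below `convergence_tol`
(default 1e-6) or `max_iterations` (default 200).

Initialization does most of the denoising work and has three stages:

1. **Temporal filtering.** Detector noise is (modelled as) white while
   walking motion lives below ~8 Hz, so the descent is seeded from
   zero-phase low-passed tracks (4th-order Butterworth, `prefilter_cutoff`
   default 7 Hz, forward-backward so event timing is unmoved). An input
   whose energy already vanishes is perfectly self-consistent, is its own
   optimum, and passes through unfiltered — preserving the exact fixed
   point.
2. **Bone normalization** to the height-derived targets.
3. **Global positioning.** The stationary camera position is estimated once
   (`estimate_camera()`: profile least squares — lateral/vertical offsets
   are closed-form given a trial camera depth, leaving a smooth 1-D
   problem), and each frame is then re-aligned laterally/vertically to its
   2D keypoints by closed-form least squares. The per-frame distance to the
   camera is the fitted pelvis depth.

## Why depth is treated asymmetrically

Monocular depth can in principle be recovered from projected scale (known
bone lengths + focal length). In practice that channel is ill-conditioned
once the skeleton estimate carries shape noise: a limb tilted toward the
camera shortens its projection exactly like extra distance does. During
development we measured depth-from-scale alignment to be several times
*worse* than the raw monocular depth estimates at centimeter-level joint
noise. The design therefore:

* keeps the raw (temporally filtered) monocular depths as the depth
  authority,
* freezes the IK anchors' depths at initialization so that the bone
  projection step cannot trade depth drift for a marginally better
  image-plane fit (without the anchor depth residual, descent decreased
  energy while increasing true error), and
* does not descend depth along the projection term.

With these choices the optimizer reduces the mean per-joint error of noisy
input on every seed tested at 1–3 cm noise, rather than merely reducing
energy.

# Step detection: honest local extrema

The carrier signal is the per-frame Euclidean distance between the ankles
(equivalently, one foot against any reference joint; with the other foot as
reference the two coincide). During a smooth walk it peaks when the moving
foot has covered the step length and dips as the feet pass. Real signals
are noisy, and frames around double support can show several spurious local
extrema per true event, so extraction proceeds in stages:

1. **Smoothing**: zero-phase Butterworth low-pass at 6 Hz (the gait
   fundamental stays below ~2 Hz even for fast walkers); zero-phase so
   extremum timing is preserved.
2. **Candidates**: an exhaustive neighbor-comparison scan; plateau runs
   emit one candidate per run endpoint. No thresholds at this stage.
3. **Honest extrema**: plateau duplicates collapse to their most extreme
   member (equal-value ties to the earliest frame); the now strictly
   alternating sequence is simplified by *persistence*: adjacent max/min
   pairs whose value difference is below `min_prominence` (default 30%) of
   the signal's full swing are cancelled pairwise, smallest first. A true
   step always swings between the step-length peak and the feet-passing
   trough; double-support ripple and noise wiggles never do. Pair
   cancellation preserves alternation by construction and keeps the best
   member of each genuine peak. The sequence is trimmed to start and end on
   a maximum — once before simplification (a recording cut mid-swing ends
   on a shallow edge trough that must not cancel the final true landing)
   and once after. Each surviving extremum reports its cluster (same-kind
   candidates within a window of a quarter step period, the period
   estimated from the autocorrelation peak of the smoothed signal) and
   takes the cluster's *earliest* member as its frame: a gait event is the
   onset of its extremal episode, which matters when a double-support dwell
   forms a plateau.
4. **Step segmentation**: each honest maximum is a landing; the landing
   side is the ankle that is forward along the walking direction (the
   principal axis of the pelvis ground-plane trajectory, oriented by net
   displacement).

## Sub-frame timing and the step-length read-off

Frame quantization alone bounds the accuracy of trial-mean step time at
roughly `1 / (fps * step_time * n_steps)` — at 24 fps and ten steps that is
worse than 0.5%, which is not acceptable for a measurement device. Both
feet decelerate into a landing with vanishing velocity *and* acceleration,
so the distance peak is locally cubic-flat, and the flank of the peak
follows an ease curve `C(u/T) = u/T - sin(2*pi*u/T)/(2*pi)` for a smooth
swing of period `T`. `segment_steps()` fits this two-sided flank model to
the raw samples around each detected peak, profiling the peak location on a
fine grid (0.05 frame) with linear least squares at each trial location;
landing times are the fitted peak locations and step intervals their
differences. The same model, evaluated at the refined landing time on the
walking-direction component of the inter-ankle vector, yields the step
length as the fitted plateau value — avoiding both the peak-rounding bias
of global low-pass filtering and the droop of plain window averaging, while
still averaging noise over the whole fitting window.

Step length uses the walking-direction *component* of the inter-ankle
vector rather than the raw 3D distance: this removes the lateral
base-of-support contribution (with a 10 cm stance width and a 70 cm step the
raw distance overshoots by ~0.7 cm).

Trial summaries: mean step time; cadence `60 / step_time_mean`; mean step
length (cm); gait speed as pelvis displacement along the walking direction
between the first and last landing divided by the elapsed time (the
walkway's definition: distance traversed over ambulation time), with
`step_length * cadence / 6000` exposed as a consistency diagnostic.
Auxiliary outputs: foot clearance above a per-trial ground plane (5th
percentile of that ankle's heights — a noise-robust stance reference), and
knee / hip-plane angle series from the standard three-joint definitions.

# The synthetic walker

`generate_walk()` builds a frontal-view walk from sampled per-step
durations and lengths (Gaussian around the scenario means, truncated, CVs
default 4%): ground-fixed stance feet; cycloidal swing-foot advance (zero
end velocity and acceleration) with a half-sine vertical lift to
`foot_clearance`; pelvis midway between the feet with a small lateral sway;
knees placed by exact two-link inverse kinematics so that *every* bone
length equals the anthropometric target in every frame (to 1e-9); anti-phase
pendulum arms and a stacked head chain populate all 21 joints. The walk
ends shortly after the last landing with the start of a closing swing, so
the last landing is an interior extremum. An optional double-support
`dwell` holds both feet down for a fixed interval after each landing,
creating genuine distance plateaus. The camera is a stationary pinhole
(defaults: 1400 px focal, 1080x1920 principal point, 1.2 m height) and the
walk is placed to end 2.2 m in front of it, starting 5-9 m away depending
on the walk length.

Noise models what the neural detectors get wrong, not how: i.i.d. zero-mean
Gaussian per joint per frame — `noise3d_sigma` per axis with the depth axis
inflated by `depth_noise_factor` (default 2; monocular depth is the weak
axis), and independent pixel noise on the rendered 2D keypoints. In the
study harness the 2D keypoints are rendered from the *clean* walk with
pixel noise: the 2D detector watches the video and does not inherit the 3D
lifter's errors.

Default study conditions (chosen once, from the operating point of elderly
walkers on an instrumented walkway): subject preferred speed ~ N(1.42,
0.32²) m/s, cadence ~ N(121.77, 14.56²) steps/min (both truncated, step
length capped at leg reach), fast condition = speed x1.25 / cadence x1.12,
trial-to-trial CV 2%, heights ~ N(1.70, 0.09²) m, 3D noise sigma 2 cm with
depth factor 2, 2D noise 1 px, 8 steps per walk at 30 fps.

What the simulator does *not* emulate — so what passing tests do not show:
temporally correlated or pose-dependent estimator error (real detector
error is both), occlusion-induced missingness bursts, foot pitch during
swing, soft-tissue or clothing artifacts, camera shake in handheld
recording, and rolling-shutter effects. Results on simulated data bound the
pipeline's algorithmic error, not a real device's total error.

# Agreement statistics

`icc()` computes intraclass correlations directly from the two-way mean
squares of a complete-case targets x raters matrix: ICC(2,k) (two-way
random effects, absolute agreement, average of k — the between-systems
validity index), ICC(2,1) (its single-measurement form), and ICC(3,1)
(two-way mixed, consistency, single measurement — the test-retest
repeatability index). A zero-variance matrix is perfect degenerate
agreement: value 1 with a flag. Classification uses the standard bins
(poor < 0.5 <= moderate < 0.75 <= good < 0.90 <= excellent).

`mean_diff_ci()` reports the mean paired difference with a seeded
percentile-bootstrap 95% CI (default 10,000 resamples; per-walk differences
are typically skewed, so no normality is assumed) and as a percentage of
the reference system's mean. `bland_altman()` reports limits of agreement
`mean ± 1.96 SD` with percent forms. `validity_report()` assembles the
standard validity table: per-parameter means (SD) per system, ICC(2,k)
across systems over all walks, ICC(3,1) within each system (targets =
subject-condition cells, repeats = trials; a flag switches to per-condition
reporting, since pooling conventions vary), Diff [95% CI] in % of the
reference mean, and the Bland-Altman block. Missing walks are dropped
complete-case per statistic and counted in a footnote. No multiple-testing
correction is applied: these are descriptive agreement measures, not
hypothesis tests.

`run_study()` wires everything into a reproducible synthetic cohort study
(defaults: 43 subjects x 2 conditions x 3 trials) with the pipeline as
system A and the simulator truth as reference system B, returning the
report, the per-trial table and a manifest sufficient to reproduce the run.
Failing trials are logged and skipped; above 20% failures the study aborts.

# Numerical choices and degenerate inputs

* Zero-phase filtering uses even reflection padding (about one second) to
  suppress edge transients; signals shorter than 7 samples pass through.
* The camera profile search brackets the camera depth strictly behind the
  nearest 3D point; collinear 3D geometry is rejected.
* Bone re-normalization refuses coincident joints (degenerate directions).
* The backtracking step size shrinks by half on rejection and grows by 1.3
  on acceptance; descent stops when no decreasing step of at least 1e-9
  remains.
* Equal-value extremum ties resolve to the earliest frame everywhere.
* Ankles coincident along the walking direction make the landing side
  undecidable and raise an error rather than guessing.
* Fewer than two honest maxima, fewer than two usable steps, or a net
  pelvis displacement under 0.2 m are reported as errors ("insufficient
  steps" / "no walk detected").

# Problem sizes

The shipped validation exercises the pipeline at: a noiseless grid of 15
scenario/frame-rate combinations (10 steps each); 60 noisy runs (6
scenarios x 10 seeds) at 2 cm joint noise; 50 random instances for the
optimizer contracts plus 30 paired runs at 1-3 cm noise; 200 random
matrices against an explicit sums-of-squares ICC oracle; bootstrap
calibration with 500 replications at n = 100; and a full 43-subject x
6-walk synthetic cohort study (258 walks). These sizes were chosen so the
whole validation completes in a few minutes on one CPU while every
criterion retains clear statistical margin.

# Known limitations

* The energy weights and allowances are fixed defaults, not tuned per
  device; a real deployment would calibrate them against its detectors.
* Depth accuracy is bounded by the (filtered) monocular depth estimates;
  the optimizer deliberately does not attempt depth-from-scale recovery.
* Step detection assumes a roughly straight walk (a single dominant
  walking direction); turning protocols would need piecewise direction
  estimation.
* Under a double-support dwell the honest-extremum frame localizes the
  smoothed plateau rather than its onset; landing-time refinement recovers
  sub-frame timing only within about a frame of the detected peak.
* The simulator's noise is white; correlated detector error will generally
  degrade real-world accuracy relative to the simulated figures.
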