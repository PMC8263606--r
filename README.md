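# gaitmetrics

Markerless gait analysis from monocular 3D pose time series, with the
method-agreement statistics used to validate camera-based gait assessment
against an instrumented walkway.

Clinical gait assessment increasingly replaces pressure-sensitive walkways
with a single smartphone camera: neural pose detectors turn the video into
per-frame 2D keypoints (pixels) and 3D keypoints (meters), and the
spatiotemporal gait parameters are computed from those. `gaitmetrics`
implements everything downstream of the detectors:

* **Anatomically constrained skeleton fitting.** A four-term energy —
  inverse-kinematics consistency with the back-lifted 2D keypoints,
  pinhole reprojection error, a temporal-smoothness hinge, and a
  depth-damping hinge — is minimized by projected gradient descent under
  *hard* bone-length constraints scaled from the subject's height
  (`E = λ_ik E_ik + λ_proj E_proj + λ_smooth E_smooth + λ_depth E_depth`),
  recovering a height-consistent, temporally smooth skeleton and the
  per-frame distance to a stationary camera.
* **Step detection via honest local extrema.** The inter-ankle distance
  `d(t)` peaks once per step (when the moving foot has covered the step
  length) and dips as the feet pass. Noisy extremum candidates are
  clustered and simplified by persistence into *honest* extrema — one per
  true gait event even when double support spawns several spurious ones —
  and landing times are refined to sub-frame precision with a
  smooth-swing peak model.
* **Gait parameters.** Per-step lengths, durations and sides; trial-level
  gait speed (m/s), cadence (steps/min), step length (cm) and step time
  (s); foot clearance and joint-angle series.
* **Method agreement.** ICC(2,k) (two-way random, absolute agreement,
  average measures), ICC(3,1) (two-way mixed, consistency, single
  measure), seeded percentile-bootstrap CIs on mean differences, and
  Bland–Altman limits of agreement `mean ± 1.96 SD`, assembled into the
  standard validity table.
* **A ground-truthed walking simulator** standing in for the neural front
  end: cycloidal swing profiles, exact bone lengths in every frame,
  controllable per-joint estimation noise (depth-inflated), and exact
  per-step ground truth — so the whole pipeline is testable end to end.

## Worked example

Simulate a noisy 8-step walk at the typical operating point of elderly
walkers (1.42 m/s, 121.8 steps/min), corrupt it with 2 cm joint noise
(depth doubled) and 1 px keypoint noise, fit the skeleton, and extract the
gait parameters:

```r
library(gaitmetrics)

sc <- gait_scenario(gait_speed = 1.42, cadence = 121.77, n_steps = 8,
                    noise3d_sigma = 0.02, noise2d_sigma = 1, seed = 3)
w   <- generate_walk(sc)                      # clean walk + ground truth
cam <- w$truth$camera_truth
raw <- add_noise3d(w$seq, sc)                 # noisy 3D estimates
raw$frames2d <- render_2d(w$seq, cam, sc$noise2d_sigma, seed = 4)$frames2d

fit <- optimize_sequence(raw, raw, height = 1.70,
                         optimizer_config(focal = cam$focal,
                                          principal_point = cam$principal_point))
fit
#> <optimized_result> 124 frames, 41 iterations (converged), energy 0.0007345 -> 0.0002475
#>   camera distance 8.36 -> 3.06 m

analyze_gait(fit$seq)
#> gait parameters (8 steps):
#>   gait speed  1.386 m/s
#>   cadence     121.21 steps/min
#>   step length 68.75 cm
#>   step time   0.495 s
```

The subject walked from 8.4 m to 3.1 m in front of the camera; all eight
steps were detected, and the four parameters land within ~1% of this
trial's ground truth (1.404 m/s, 121.60 steps/min, 69.11 cm, 0.493 s).

To compare the pipeline against a reference system over a whole cohort:

```r
st <- run_study(study_config(n_subjects = 6, trials_per_condition = 3,
                             noise3d_sigma = 0.02, seed = 11))
st$report   # per parameter: mean (SD) per system, ICC(2,k), ICC(3,1),
            # Diff [95% CI] in % of reference mean, Bland-Altman limits
```

A thin command-line driver over the same functions is installed at
`inst/cli/gaitmetrics.R` (`simulate`, `optimize`, `events`, `analyze`,
`validate`, `run-study`).

## Layout

```
R/                  implementation
tests/testthat/     unit, property and acceptance tests
scripts/            acceptance.R (validation runner)
vignettes/          methods vignette (models, parameters, design choices)
inst/extdata/       anthropometric proportion table (JSON)
inst/cli/           command-line driver
```
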