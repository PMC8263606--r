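Package: gaitmetrics
Title: Markerless Gait Analysis from Monocular 3D Pose Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Back end for smartphone-camera gait assessment from per-frame 2D
    and 3D skeleton keypoints. Fits an anatomically constrained, temporally
    smooth 3D skeleton sequence to noisy monocular pose estimates by
    minimizing a four-term energy (inverse kinematics, reprojection,
    smoothness, depth damping) under hard bone-length constraints derived
    from the person's height, and recovers the per-frame distance to a
    stationary camera. Detects steps on the inter-ankle distance signal via
    clustering of noisy extremum candidates into honest local extrema, and
    computes spatiotemporal gait parameters (gait speed, cadence, step
    length, step time) plus auxiliary kinematics (foot clearance, joint
    angles). Includes a parametric kinematic walking simulator with exact
    ground truth, and the method-agreement statistics used to validate such
    systems against an instrumented walkway: ICC(2,k) and ICC(3,1) from
    two-way mean squares, bootstrap confidence intervals on mean differences,
    and Bland-Altman limits of agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
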