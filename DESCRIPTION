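Package: gaitkit
Title: Markerless Gait Analysis from Pose-Estimation Keypoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for video-based gait analysis from 2D pose-estimation
    keypoint trajectories: trajectory despiking, gap filling and zero-lag
    Butterworth filtering; heel-strike and toe-off detection from the ankle
    motion relative to the hip centre; temporospatial gait parameters
    (stride, step, stance, swing, double support, cadence, step length,
    gait speed); sagittal hip, knee and ankle angle series and range of
    motion; and method-agreement statistics against a reference
    motion-capture system (mean absolute error, linear regression,
    Bland-Altman limits of agreement). A synthetic gait generator with
    exact ground truth emulates treadmill and overground walking, lateral
    and near-frontal camera views, landmark jitter, and occlusion-driven
    visibility dropout, so every stage is testable without recorded video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
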