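Package: stereogait
Title: Two-Camera Markerless Gait Analysis with Stereo Triangulation of Pose Keypoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested measurement chain for markerless gait analysis from two
    calibrated consumer cameras. Per-frame 2D skeleton keypoints (OpenPose
    18-keypoint dialect) from the two views are undistorted and triangulated
    into 3D joint-center trajectories, synchronized against a marker-based
    reference stream through a wrist-to-hip tap gesture, and rigidly aligned
    (Kabsch) into a common laboratory frame. Gait events are detected from the
    filtered ankle-speed signal by automatic hysteresis thresholds, yielding
    step length, stance and swing times from complete steps only. The
    evaluation layer computes per-node RMS trajectory errors after optimal
    rigid alignment, Bland-Altman agreement of spatio-temporal parameters and
    a two-level factorial analysis of variance over camera distance, gait
    direction and video resolution. A kinematic walking simulator with known
    ground truth emulates the laboratory: the reference optoelectronic stream,
    the two camera keypoint streams with noise, dropout and a known time
    offset, and the stereo calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, yaml, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
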