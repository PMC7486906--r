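Package: poseRig
Title: Multiview Markerless 3D Pose Reconstruction and Behavior Analysis for Freely Moving Primates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for markerless multi-camera motion capture of freely moving
    primates in large enclosures. Provides calibrated pinhole camera models and
    robust multiview triangulation (direct linear transform, mean-shift, and
    RANSAC), annotation-efficiency machinery (keyframe selection, crop-window
    computation, geometric verification, and cross-view label propagation),
    physically plausible kinematic-chain pose refinement with limb-length and
    temporal-smoothness cues, and downstream behavior analytics (canonical pose
    features, embedding and clustering, k-nearest-neighbor action
    classification, action transitions, two-animal tracking, action
    co-occurrence, and proxemics). A built-in synthetic studio simulates the
    camera rig, an articulated 13-landmark skeleton executing scripted actions,
    and noisy per-view detections, so the full pipeline can be exercised and
    evaluated without image data or a trained detector.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    mclust
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
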