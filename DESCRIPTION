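Package: stereopose
Title: Calibration-Free Stereo 3D Human Pose Reconstruction and Exercise Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs 3D human pose trajectories from two synchronized,
    roughly perpendicular camera views without prior stereo calibration.
    Per-frame 2D joint detections (pixel coordinates plus visibility scores)
    are undistorted through a Brown-Conrady lens model, the relative camera
    geometry is self-calibrated by robust least-median-of-squares essential
    matrix estimation, and joints are triangulated by the Direct Linear
    Transform. Includes an orthogonal-combination reference fusion, optional
    zero-phase trajectory filtering with grid-search parameter selection,
    conversion of optical motion-capture marker sets to ground-truth joint
    positions, evaluation by similarity alignment (RMSE/MPJPE) and 3D
    knee/hip joint angles, and a synthetic squat generator with a virtual
    stereo rig for validation of the full pipeline, including discrimination
    of correct from incorrect squat execution by joint-angle extremes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
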