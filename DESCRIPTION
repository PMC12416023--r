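Package: uplimb
Title: Upper-Limb Joint Kinematics and Markerless Motion-Capture Agreement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for validating single-camera
    markerless motion capture of the upper limb against a marker-based
    reference. Provides quaternion and rotation-matrix algebra with SLERP
    smoothing and intrinsic Euler decomposition, a scalable kinematic chain of
    the upper limb with joint limits and virtual keypoints, scripted movement
    generation and two-system measurement simulation, zero-phase Butterworth
    filtering, resampling and cross-correlation time alignment, joint-angle
    computation by the coordinate-frame and inverse-kinematics methods, and
    repeated-measures Bland-Altman agreement statistics (variance partition,
    bias, limits of agreement, RMSE) with one-way comparison ANOVAs and
    Cohen's f effect sizes.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
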