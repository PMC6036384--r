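Package: fidseg
Title: Automatic Detection and Pose Estimation of an MRI Fiducial Marker Device
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Localizes a four-marker external fiducial device in 3D magnetic
    resonance image volumes acquired with heterogeneous clinical pulse-sequence
    geometries (anisotropic voxels, slice gaps, oblique planes). Implements the
    full detection pipeline: histogram-based noise thresholding, 26-connected
    component analysis with marker-volume size gates, iterative multi-threshold
    signal segmentation, shape discrimination, and constellation matching of
    candidate centers-of-mass against the known pairwise marker separations.
    Reports the device pose (group center-of-mass, base-plane normal, spherical
    orientation angles) and the rigid transform to the device frame. Includes a
    synthetic MR acquisition simulator (slice thickness and gap, scan-plane
    rotation, partial-volume supersampling, quantized noise) and evaluation
    routines for detection rate, inter-marker spacing accuracy, and pose
    repeatability.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
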