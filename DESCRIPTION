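Package: cb3d
Title: Extrinsic Calibration of 3D Scanning Systems with a Hole-Pattern Checkerboard
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-capture extrinsic calibration for pairs of 3D scanning
    systems (structured light, active stereo, time of flight) using a planar
    calibration target with through-holes arranged in a checkerboard-parity
    grid. From one depth capture of the target per camera, the package detects
    the hole centers (background cropping, RANSAC plane segmentation, PCA
    projection, binary rasterization, connected components, per-hole medians),
    estimates the least-squares rigid transform between the two coordinate
    frames, optionally refines it with iterative closest point, and scores
    registration quality with an overlap-region RMSE/SD metric. A synthetic
    depth-capture generator with ground-truth poses makes every stage testable
    without camera hardware. Point clouds are read and written as PLY, PCD and
    XYZ; transforms as JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
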