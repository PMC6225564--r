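Package: siftreg
Title: Feature-Based 3D Registration of CT Angiography to Cone-Beam CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic feature-based registration of a large field-of-view
    preoperative CT angiography volume to a small field-of-view intraoperative
    cone-beam CT volume. Detects 3D scale-invariant (SIFT-style) keypoints in
    both volumes, matches them by mutual nearest-neighbour descriptor distance,
    estimates an affine transform with a two-stage geometry-aware RANSAC
    (field-of-view pruning and transform-guided local re-matching between the
    stages), and fits a final 3D thin-plate-spline map on the surviving inlier
    correspondences. Includes landmark-based target-registration-error
    evaluation, image fusion utilities, and a synthetic abdominal phantom
    generator with known ground-truth deformation so the whole pipeline can be
    exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
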