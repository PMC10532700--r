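Package: postop3d
Title: Automatic 3D Postoperative Evaluation of Osteotomy Interventions from CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fully automatic three-dimensional postoperative outcome
    quantification for osteotomy-type orthopaedic interventions such as the
    periacetabular osteotomy (PAO). Detects bone cuts in postoperative CT as
    labelled regions and fits one plane per cut by principal component
    analysis; quantifies fragment repositioning by masked two-stage rigid
    registration (normalized correlation metric, regular-step gradient
    descent); and quantifies screw implants by metal thresholding, iterative
    3D Hough line detection and fast voxel traversal ray tracing. A synthetic
    CT phantom generator provides full ground truth (cut planes, fragment
    transform, callus labels, screws) for every stage, and a compact 3D U-Net
    training harness supports learning-based cut and pelvis segmentation at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
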