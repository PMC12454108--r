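Package: bovigait
Title: Overhead-View RGB-D Gait Analysis and Lameness Classification for Dairy Cows
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and grading lameness in dairy cows from
    overhead RGB-D recordings. Implements the depth preprocessing chain
    (range clipping, void-aware bilateral and median filtering,
    nearest-neighbour hole filling, void-rate screening), six quantified
    gait and posture features computed from eight back keypoints and depth
    sequences (back curvature, movement asymmetry index from dense optical
    flow, vertical oscillation of back and head, trunk inclination, lateral
    sway amplitude of the spine), unbiased feature screening by random-forest
    Gini importance with permutation-importance correction and
    Benjamini-Hochberg false discovery rate control, multi-feature fusion
    classification into sound, mild and severe lameness with random forest,
    k-nearest neighbours and support vector machines, keypoint evaluation
    metrics (PCK, AP/AR), and desk-testable forward passes of the adaptive
    sparse self-attention, feature-refinement feedforward and adaptive
    graph-convolution modules. A class-conditional gait simulator generates
    synthetic walking sequences for testing every stage without farm data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, Rcpp, ranger, class, e1071, igraph,
    jsonlite, png
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), randomForest, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
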