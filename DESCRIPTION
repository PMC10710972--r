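Package: capfeat
Title: Adaptive-Threshold FAST Detection and FREAK Matching for Capsule Endoscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature detection, description and matching for low-texture,
    unevenly illuminated images such as capsule endoscopy frames. Detects
    corners with a FAST segment test whose threshold adapts per pixel to the
    local gray-level contrast of the 16-pixel Bresenham circle, over an
    8-level Gaussian scale-space pyramid. Describes keypoints with a retinal
    (FREAK-style) binary descriptor: 43 Gaussian-smoothed sampling points on
    seven concentric circles, 903 pairwise sign comparisons reduced to 512
    informative bits. Matches descriptors by Hamming distance, filters with
    grid-based motion statistics (GMS) and verifies with RANSAC homography
    estimation. Includes seeded synthetic image generators (texture,
    endoscopy-like illumination, checkerboard), rotation-sweep and
    frame-tracking evaluation harnesses, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    generics,
    rlang,
    ggplot2,
    png,
    jpeg,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
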