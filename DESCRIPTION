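Package: guavapose
Title: Fruit Detection and Branch-Relative 3D Pose Estimation from RGB-D Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects individual fruits and estimates a collision-avoiding,
    branch-relative 3D pose for each one from an aligned RGB-D frame and a
    three-class (background/fruit/branch) segmentation map. Depth pixels are
    back-projected through a pinhole camera model to a millimetre point
    cloud; fruits are separated by Euclidean clustering with an exact radius
    search and localised by bounding-box means or least-squares sphere fits;
    branches are thinned to morphological skeletons and reconstructed as 3D
    line segments by sequential RANSAC; each fruit is assigned its nearest
    branch segment and given the unit vector from the nearest branch point
    to the fruit centre as its approach pose. Includes segmentation,
    detection and pose evaluation metrics (per-class accuracy and IOU,
    precision/recall, median angular error and median absolute deviation)
    and a ray-cast synthetic scene generator (spherical fruits on
    cylindrical branches) so the whole pipeline can be verified against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    yaml,
    EBImage
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
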