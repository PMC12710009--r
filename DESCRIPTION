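Package: soycloud
Title: Plot-Level Soybean Phenotyping from Colored UAV Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates plot-level soybean grain yield and discriminates
    lodging severity from colored canopy point clouds. Raw plot clouds are
    cleaned (statistical outlier removal, RANSAC ground-plane segmentation),
    voxel-downsampled to a fixed point count, and augmented per point with
    seven visible-band vegetation indices to form 13-channel inputs
    (x, y, z, R, G, B, EXR, EXG, EXGR, MGRVI, RGRI, PPRb, VARI). These feed
    permutation-invariant point-cloud networks (a PointNet-style backbone and
    a residual variant) trained single-task or multi-task with fixed or
    homoscedastic-uncertainty loss weighting. Also provides the classical
    plot feature table (vegetation-index means, gray-level co-occurrence
    texture, canopy height from surface-model differencing, convex hull and
    height-density structure metrics), micro-averaged cross-validated
    evaluation, top-k accuracies, and Global Moran's I diagnostics of
    residual spatial autocorrelation. A synthetic canopy generator emulates
    three-ridge soybean plots so the whole pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    FNN,
    yaml,
    jsonlite,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse,
    tiff,
    png,
    EBImage,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
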