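Package: treeskel
Title: Reconstruction of Tree Perennial-Tissue Skeletons from Point Clouds
Version: 1.0.0
Authors@R:
    person("treeskel", "developers", email = "treeskel@example.org",
           role = c("aut", "cre"))
Description: Reconstructs the woody skeleton (topology and per-segment radii)
    of botanical trees from surface-sampled 3D point clouds such as those
    produced by terrestrial LiDAR scanning. Builds a radius-constrained
    neighbourhood graph, computes geodesic distances from the trunk base,
    partitions the cloud into geodesic level sets, segments each level into
    branch cuts, and links the cut centroids into a rooted curve skeleton
    with false-tip pruning, smoothing and radius estimation. Includes a
    stochastic L-system generator of synthetic trees with a virtual-scanner
    surface sampler for end-to-end validation, botanical axis-order
    decomposition and reconstruction-quality metrics, point-cloud readers
    and writers (ASCII XYZ, ASCII and binary PLY), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    optparse,
    withr,
    FNN,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
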