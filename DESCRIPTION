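Package: hiervess
Title: Hierarchical Random-Walker Segmentation and Morphometry of Vascular Networks in Large 3D Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic, seed-based segmentation of vascular structures in
    large 3D light-sheet microscopy volumes using a hierarchical random-walker
    scheme over a bricked octree level-of-detail pyramid, with bounded-memory
    (out-of-core) brick access. Includes binary-mask post-processing (median
    smoothing, cavity filling, spurious-fragment removal via brick-streaming
    connected components), centerline extraction by 3D topology-preserving
    thinning, vessel-graph construction with radius estimation from an
    anisotropic Euclidean distance transform, scale-independent bulge-size
    pruning of spurious branches, and vessel morphometrics (diameter histogram,
    size classes, length, straightness, volume). A deterministic phantom
    generator produces branching vessel trees with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
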