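Package: beadnet
Title: Reference-Free Spatial Reconstruction of Cell-Bead Tagging Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers two-dimensional cell positions from the bipartite
    cell-bead association network formed incidentally by barcode diffusion
    in Slide-tags-style spatial transcriptomics experiments. Provides the
    network data model with initial UMI and singleton filtering, unipartite
    projection, random-walk skip-gram node embedding with neighbor-preserving
    reduction to 2D, transform-invariant fidelity metrics (correlation of
    pairwise distances and K-nearest-neighbor overlap), iterative DBSCAN-based
    edge pruning, alpha-shape boundary detection with thin-plate-spline shape
    regularization, a Fickian diffusion plus random-chord mixture model for
    bead diffusion-coefficient estimation, and a ground-truthed diffusion
    network simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    Matrix,
    data.table,
    minpack.lm,
    jsonlite,
    grDevices,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
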