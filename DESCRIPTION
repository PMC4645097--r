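Package: vasculonet
Title: Extraction and Topological Analysis of 3D Microvascular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn 3D volume images of luminally stained blood
    vessels into geometric network descriptions ("topology maps") and to
    analyse their topology. Includes local thresholding, ray-casting
    "insideness" lumen filling that closes staining gaps in vessel walls,
    largest-component isolation, topology-preserving 3D thinning,
    centerline tracing into a node/segment graph with per-point radii,
    diameter/length/volume summaries, shortest-path branch counts from
    feeder vessels, nearest-vessel distance fields and void detection,
    morphology-based selection of putative high endothelial venules,
    subregion and 2D virtual-histology statistics, and export to Amira
    SpatialGraph and CMGUI interchange formats. A parametric vascular-tree
    phantom generator with exact ground truth supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
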