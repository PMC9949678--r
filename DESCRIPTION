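Package: fusomekit
Title: Reconstruction and Growth Modelling of the Germline Cyst Fusome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of the fusome, the membranous
    organelle that permeates insect germline cysts through their ring canals.
    Provides cyst lineage trees with division rules, enumeration of reachable
    cyst topologies up to isomorphism, and subtree-embeddability tests;
    ring-canal-guided recursive segmentation of 3D fusome masks into per-cell
    fragments with canonical cell labelling; an additive fusome
    growth/inheritance model fitted to per-cell volume fractions by
    grid-search least squares; and a synthetic-data generator producing both
    model-drawn volume tables and rendered voxel images with known ground
    truth.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
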