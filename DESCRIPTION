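Package: AlphaPore
Title: Alpha-Complex Based Extraction, Ranking and Profiling of
    Channels and Pores in Biomolecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts geometrically feasible channels and pores from
    protein structures using the weighted Delaunay (regular)
    triangulation and the alpha complex of the van der Waals ball
    model.  Channels are represented as paths of empty-space
    tetrahedra, ranked by persistence-based endpoint selection, and
    transmembrane pores are scored by length, bottleneck radius and
    multi-scale straightness.  Radius, physico-chemical, conservation
    and electrostatic profiles are computed along channel centerlines,
    with 2D box-diagram, SVG, JSON and PyMOL exports.  Includes
    synthetic structure generators (tubes, blobs, shells, multi-pore
    barrels) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    igraph,
    jsonlite,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
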