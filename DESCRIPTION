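Package: foldnet
Title: Durer Net Enumeration and Foldability Descriptors for Polyhedra
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Exhaustive enumeration of edge unfoldings (Durer nets) of the
    Platonic solids and user-supplied convex polyhedra, with symmetry
    reduction to distinct nets, exact planar unfolding, and the topological
    and geometric descriptors used to study self-folding of polyhedral
    shells such as icosahedral viral capsids: vertex connections, leaves,
    spanning-tree degree distributions and diameters, boundary degree
    circuits, radius of gyration, and convex-hull compactness metrics.
    Includes matrix-tree cross-checks, Schlegel layouts, magnet-map design
    validation, Caspar-Klug triangulation numbers, OFF mesh input/output,
    SVG rendering, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
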