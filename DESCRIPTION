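Package: tactostele
Title: Spatial Order Statistics for Vascular Bundle Patterns in Monocots
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the degree of spatial order in one- and
    two-dimensional arrangements of plant vascular bundles observed in
    transverse sections. Implements the Clark-Evans nearest-neighbour R
    index for line, ring and planar patterns with Delaunay-based neighbour
    identification; the doubly-truncated exponential ("ski-jump") model of
    leaf intervein distances with exponential gap growth, asymmetric vein
    insertion and binomial smoothing; the preprocambium cell-spacing model
    (P/S/F conversion rule) with a stochastic simulator, exact permutation
    and combination enumeration and the binomial ("children's slide")
    spacing distribution; seeded synthetic generators for every input
    class; and a report pipeline tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
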