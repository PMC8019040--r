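Package: alphamorph
Title: Landmark-Free Alpha-Shape Complexity Analysis of 3D Anatomical
    Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the three-dimensional shape complexity of closed
    anatomical surface meshes (for example endocasts of the vaginal lumen)
    without homologous landmarks. The mesh interior is filled with uniform
    random points, a family of alpha shapes is fitted across a logarithmic
    grid of refinement coefficients scaled by a point-cloud reference
    length, and the refinement at which the alpha-shape volume matches the
    true mesh volume defines a scalar "alpha complexity" (its reciprocal).
    Per-vertex complexity heatmaps, multi-scale volume profiles, principal
    component morphospaces, and phylogenetic comparative tests (Pagel's
    lambda, ancestral states, PGLS with a Pagel correlation structure,
    phylogenetic ANOVA and MANOVA) are provided, together with parametric
    generators of tube-like benchmark meshes and simulated comparative
    data with known evolutionary parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    reticulate,
    RANN,
    ape,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme,
    withr
Config/testthat/edition: 3
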