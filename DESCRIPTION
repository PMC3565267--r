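Package: polypack
Title: Monte Carlo Simulation and Local-Order Analysis of Athermal Hard-Sphere Polymer Packings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and structural analysis of dense packings of
    freely-jointed chains of tangent hard spheres. Provides a Monte Carlo
    engine with configurational-bias local moves and simplified
    connectivity-altering (end-bridging) moves in the fixed-composition
    ensemble, an isotropic compression protocol with affine chain
    repositioning, periodic Voronoi tessellation with inertia-tensor shape
    descriptors (asphericity, acylindricity, relative shape anisotropy),
    a characteristic-crystallographic-element norm that classifies each
    site as hcp-, fcc- or fivefold-like, crystallinity order parameters,
    pair correlation functions and flipper mobility statistics for
    detecting the entropy-driven disorder-order transition.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
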