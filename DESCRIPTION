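Package: navmaps
Title: Navigability and Hyperbolic Geometry of Spatially Embedded Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study how well the topology of a spatially embedded
    network (a connectome) is encoded in a geometric layout. Implements the
    greedy routing protocol with success-rate and stretch statistics,
    maximum-likelihood embedding of a network into the two-dimensional
    hyperbolic disk via the S1/H2 hidden-metric-space model, three
    randomization baselines (position swap, degree-preserving and
    cost-preserving link rewiring), and geometric cartography statistics
    (critical-gap angular communities, normalized mutual information,
    angular-localization permutation tests). Includes generators for
    synthetic S1-model networks with known ground truth and for
    three-dimensional spatial networks with distance-dependent connectivity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
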