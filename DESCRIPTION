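Package: fishinv
Title: Invasion Metrics and Driver Analysis for Freshwater Fish Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying and explaining large-scale invasion of
    freshwater fish communities. Computes body-mass-corrected abundance from
    ordinal field abundance classes, per-site invasion degree, and a
    colonization-by-prevalence invasiveness ranking of exotic species.
    Engineers per-site invasion drivers, including livestock units, a
    configurable eutrophication proxy, inverse-distance interpolation,
    radius aggregation, and a bounded river-fragmentation index from
    categorized migration barriers on a river network. Provides a boosted
    regression tree modelling protocol with variable-importance reduction,
    cross-validated deviance explained, Moran's I residual diagnostics and a
    Voronoi-neighborhood spatial autocovariate, plus collinearity screening,
    four-group variation partitioning with permutation tests, and redundancy
    analysis with per-axis permutation tests. A synthetic landscape and
    community generator supplies test beds with known planted structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    igraph,
    rlang,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    xgboost,
    optparse
Config/testthat/edition: 3
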