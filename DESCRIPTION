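Package: conemosaic
Title: Voronoi-Domain Statistics for Cone Photoreceptor Mosaics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Spatial analysis of cone photoreceptor mosaics represented as
    planar point patterns. Computes Voronoi-domain area distributions over a
    rectangular sampling window with boundary-cell exclusion, the g1 skewness
    of the domain-area distribution, and the coefficient of clustering (the
    ratio of the global coefficient of variation of domain areas to the mean
    local coefficient of variation among each cell's Voronoi neighbours),
    which discriminates ring-patterned degenerating mosaics from homogeneous
    ones. Includes readers for cell-coordinate tables and annotated dot-map
    images, a seeded generator of ring-clustered and hard-core homogeneous
    synthetic mosaics, per-group mean/SEM summaries with two-sample t tests,
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deldir,
    jsonlite,
    Rcpp,
    grDevices,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    EBImage,
    png,
    readxl,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
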