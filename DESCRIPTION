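Package: ecoredundancy
Title: Functional Redundancy, Hull-Based Functional Richness and
    Dissimilarity Modelling for Presence/Absence Communities
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing taxonomic and functional diversity of
    presence/absence community data. Species are grouped into functional
    entities (unique combinations of categorical traits) from which
    per-site functional redundancy and vulnerability are computed.
    Convex-hull functional richness (FRic) in a Gower/PCoA trait space is
    standardised against a fixed-margin swap null model. Pairwise
    taxonomic and functional Jaccard dissimilarities feed generalized
    dissimilarity models (monotone I-spline transforms fitted by
    non-negative iteratively reweighted least squares under a
    negative-exponential link) with deviance partitioning into
    environmental and geographic components, and smooth additive models
    relate diversity metrics to climate and landscape predictors. A
    synthetic landscape and community generator with known ground truth
    supports end-to-end testing without atlas data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    mgcv,
    splines,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    cluster,
    optparse
Config/testthat/edition: 3
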