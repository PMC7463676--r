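Package: metafoot
Title: Metabolic Footprint Stratification of OGTT Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stratifies population cohorts characterised by a three-point
    (0/30/120 min) oral glucose tolerance test into metabolic phenotypes and
    profiles the resulting clusters against population percentiles (the
    "metabolic footprint").  Provides a full panel of OGTT-derived indexes of
    insulin secretion, resistance and clearance, fatty-liver scores and
    estimated glomerular filtration rate; a multilayer self-organizing map on
    a 27-unit toroidal hexagonal grid; Ward hierarchical clustering of the
    map units with silhouette-based model selection and bootstrap clusterwise
    Jaccard stability; percentile-bin cluster profiling and radar-plot
    footprint coordinates; and a synthetic cohort generator with planted
    metabolic archetypes so the whole pipeline is testable without access to
    any patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    ape
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
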