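Package: chondromir
Title: miRNA-mRNA Screening and Kinetic Modelling of miR-199-Driven Chondrogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal miRNA-mRNA interaction screening and
    ordinary-differential-equation modelling of miR-199a/b-5p regulated
    chondrogenesis. Implements timepoint-wise significance filtration,
    hypergeometric pathway over-representation with recurrence across
    timepoints, anticorrelation plus multi-database-vote interaction
    filtering, scaled log2 fold-change trajectory ranking, rank-based
    target aggregation with chi-square overlap testing, qPCR
    percent-of-control conversion to model units, deterministic simulation
    of initial and enhanced kinetic models with timed miRNA-inhibition
    events, SBML exchange, particle swarm calibration, and mean-squared-error
    model assessment. A synthetic-data generator with known ground
    truth makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    xml2
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
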