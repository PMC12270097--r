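Package: holocomm
Title: Holobiont Community Assembly Analysis for Coral Hosts
Version: 0.1.0
Authors@R:
    person("Holocomm", "Developers", email = "holocomm@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the drivers of coral holobiont community
    assembly: host genetic structure (identity-by-state distances, clone
    pruning, hierarchical cluster assignment, Weir-Cockerham FST, UPGMA
    trees), amplicon sequence variant (ASV) community processing (replicate
    aggregation, prevalence and read-count filters, correlation-based ASV
    grouping, Hellinger standardisation, Bray-Curtis distances),
    BLAST-consensus subtype taxonomy, marginal-term PERMANOVA and
    group-dispersion tests on distance matrices, and random-forest based
    variable importance for ordination axes ("RDA forest").  A
    Dirichlet-multinomial synthetic-data generator with known planted
    cluster, site and size-class effects makes the full pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
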