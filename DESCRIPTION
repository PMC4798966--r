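Package: mlsel
Title: Multilevel Selection Models of Cooperation via Partner Choice and
    Partner Fidelity Feedback
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and accounting toolkit for the evolution of
    cooperation under multilevel selection. Implements Price-equation
    bookkeeping for grouped cooperator/cheater populations (exact rational
    and floating-point modes), a deterministic group-reproduction game with
    tunable group assortment and group culling, a toxin-antitoxin
    anti-competition model in well-mixed and spatially structured (lattice)
    environments, proportional tit-for-tat in an iterated within-group
    public-goods game, and a nested mtDNA -> mitochondrion -> cell ->
    organism simulator in which each pro-cooperation mechanism (replication
    advantage, organelle-level proliferation feedback, selective import,
    asymmetric segregation, mitophagy, apoptosis, germline bottleneck,
    organism-level selection) is a toggleable operator annotated as partner
    choice or partner fidelity feedback at its entity level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
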