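Package: chainABM
Title: Agent-Based Simulation of Follow-the-Leader Cell Chain Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Lattice agent-based models of follow-the-leader chain migration
    as observed in embryonic neural crest cells. Implements three rule
    systems on a tri-state site grid (Closed/Open/Occupied): an
    extracellular-matrix model in which trailing cells follow a path of
    least resistance, a contact model in which filopodial contacts guide
    movement, and a hybrid of the two. Provides the formal chain-persistence
    statistic (at least six sequential agents moving towards the target at a
    minimum velocity), replicate batches, exhaustive and random parameter
    sweeps, and the accompanying statistical toolkit (mean and standard
    error summaries, Tukey-Kramer multiple comparisons versus a baseline,
    and high-persistence sub-group analysis with Pearson correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
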