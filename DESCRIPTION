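Package: addnet
Title: Activity-Dependent Degeneration in Coupled Neural Mass Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a large-scale brain network of coupled alpha-rhythm
    neural masses wired by a structural cortical connectome, and models
    progressive network degeneration in which synaptic couplings are weakened
    as a function of recent local spike density ("activity-dependent
    degeneration"), alongside an activity-independent control. Provides the
    downstream analysis chain: band-limited spectral power, synchronization
    likelihood functional connectivity, graph-theoretic metrics (clustering,
    path length, small-world indices, Newman modularity optimized by
    simulated annealing), hub classification from a degree sequence, and
    experiment drivers that relate structural connectivity to simulated
    neuronal activity at baseline and along degeneration trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    signal,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
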