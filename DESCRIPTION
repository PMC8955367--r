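Package: wkpnet
Title: Phase-Locking Brain Networks and K-Order Propagation Node Importance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds functional brain networks from multichannel narrowband
    signals via the phase locking value (PLV), binarizes them against a
    surrogate-data significance threshold, and ranks node importance with the
    weighted K-order propagation number (WKPN) algorithm: counts of nodes
    reachable within K hops, weighted across propagation orders by network
    structure entropy. Includes weighted degree centrality and weighted
    PageRank comparators, an SVM harness that classifies two task states from
    node-importance feature vectors, spectral utilities (zero-phase band
    filtering, Welch band power, paired between-state tests), and a
    coupled-oscillator synthetic-signal generator with controllable pairwise
    phase coupling for end-to-end calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    igraph,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
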