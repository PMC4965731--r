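Package: nettop
Title: Network Topology Features for Disease-Gene Prioritization
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes thirteen topological measures (degree, coreness,
    clustering coefficient, betweenness, harmonic closeness, proximity
    prestige, barycenter score, eigenvector centrality, Katz status index,
    subgraph centrality, within-module z-score, k-step Markov centrality,
    and Burt's structural-hole constraint) for every vertex of an
    undirected gene or protein network, labels vertices with a disease
    signature gene set, balances the skewed label distribution with SMOTE,
    classifies with bagged decision trees and RUSBoost under fold-honest
    stratified cross-validation, and ranks features by permutation accuracy
    importance, Gini impurity importance, their geometric-mean combined
    score, and backward elimination.  Includes a synthetic scale-free study
    generator with planted disease-gene labels for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    rpart,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
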