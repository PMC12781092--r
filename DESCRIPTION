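Package: signet
Title: Sign Annotation of Protein-Protein Interaction Networks from
    Perturbation Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotates each edge of a protein-protein interaction (PPI)
    network with an activation/repression sign. The influence of an edge
    is quantified by differential network propagation: a random walk with
    restart is seeded at each knockout gene on the full network and on a
    "defective" network with that edge zeroed, and propagation-score
    differences are averaged over the knockout's up- and down-regulated
    target sets. These differential-flow features feed a random-forest
    classifier whose output is a per-edge probability of repression
    (the S-score). Predicted signs are validated by multiplicative
    shortest-path sign-product reconstruction of knockout responses and
    anchor/terminal phenotypes, and by hypergeometric enrichment of
    functional terms among genes adjacent to predicted-negative edges.
    A synthetic benchmark generator implementing the multiplicative
    path-sign model provides planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    randomForest,
    pROC,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
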