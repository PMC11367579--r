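Package: kemenet
Title: Kemeny-Constant Variational Clustering of Kinetic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grains Markov chains represented as kinetic networks by
    minimizing the loss of the Kemeny constant, the sum of the chain's
    relaxation times. The change of the Kemeny constant under a soft
    node-to-cluster assignment is made differentiable through a
    local-equilibrium lumping path, and optimized by populations of small
    graph-neural-network partitioners (GraphSAGE or GATv2 encoders combined
    with linear or transformer decoders) trained in parallel with Adam.
    Includes exact spectral kinetics (equilibrium distributions, mean first
    passage times, Kemeny constants), synthetic kinetic-network generators
    (stochastic block models via the random-walk Laplacian and a four-well
    one-dimensional potential chain), nine node-feature families, and
    partition-quality metrics (modularity, cut size, Davies-Bouldin index).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    mclust,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
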