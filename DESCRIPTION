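Package: prsnet
Title: Perturbation-Response Scanning of Cellular Networks
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Elastic-network (Gaussian network model) analysis of cellular
    networks such as genetic interaction profile similarity networks.
    Builds thresholded similarity networks, computes the Laplacian
    pseudo-inverse covariance and the perturbation-response scanning (PRS)
    matrix with effectiveness and sensitivity profiles, selects sensor and
    effector genes, detects their clusters and antenna motifs, compares
    observed statistics against degree-preserving connected rewiring null
    models and permutation tests, extracts maximum-information shortest
    paths between effector and sensor clusters, and performs GO enrichment
    with a resampling-based false discovery rate. Includes a synthetic
    core-periphery network generator with planted antenna clusters for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
biocViews: NetworkInference, GraphAndNetwork, SystemsBiology, GO
RoxygenNote: 7.3.3
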