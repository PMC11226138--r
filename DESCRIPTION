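Package: netsevd
Title: Network-Constrained Sparse Spectral Analysis of Differential Gene
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sparse eigendecomposition of normalized graph Laplacians under
    L1 plus quadratic-Laplacian (network-constrained) regularization
    (Net-sEVD), and the ssDGN procedure built on it: a spectral distance
    between two phenotype-specific gene networks and a permutation test
    that flags differentially regulated sub-networks.  Includes a Gaussian
    graphical model simulator (random, cluster, scale-free and hub
    precision structures), lasso neighborhood-selection estimation of gene
    regulatory networks, and an end-to-end drug-sensitivity pipeline that
    splits cell lines by response quartiles, screens top-variance genes,
    extracts top-weight-edge sub-networks and reports resistance markers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    igraph,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
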