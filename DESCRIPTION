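Package: syncore
Title: Synchronization Cores and Modular Dynamics of Discrete-Time Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the discrete-time dynamics of recurrent
    tanh neural networks ("neuromodules") and of pairs of such modules
    coupled so that they can synchronize completely.  Builds coupled
    systems, verifies the synchronization condition, computes the
    synchronization matrix w+ and the obstruction matrix w-, classifies
    couplings as generative or conservative, assesses stability of the
    synchronization manifold through obstruction-matrix eigenvalues and
    transversal Lyapunov exponents, enumerates and classifies coexisting
    attractors from random initial conditions, scans bifurcation diagrams,
    and decomposes even-dimensional networks into synchronizable
    submodules.  Compiled kernels keep long orbit iterations and
    QR-based Lyapunov spectra fast.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
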