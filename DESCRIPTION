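Package: ounet
Title: Reconstruction and Analysis of Linear Stochastic Brain Networks
    from Prescribed Power Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for reverse-engineering functional connectivity matrices
    of multivariate Ornstein-Uhlenbeck processes whose dynamics reproduce a
    prescribed multi-band power spectrum. The inverse eigenvalue problem is
    solved with an isospectral gradient flow subject to sparsity (prescribed
    zero entry) constraints. The package also provides the full forward and
    analysis stack: stochastic simulation of the network dynamics, analytic
    and Welch power spectra, coherence and phase spectra, stationary
    covariance in closed form, Tononi-Sporns-Edelman neural complexity,
    nodal-strength hierarchy, node-removal spectral perturbation, a census
    of signed structural motifs among hub nodes, and bootstrap tests for
    group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
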