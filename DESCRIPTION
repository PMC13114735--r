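Package: rumornet
Title: Turing Pattern Analysis for SIR Rumor Propagation on Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates an SIR-type rumor propagation model with logistic
    growth and nonlinear (second-order) incidence on complex networks,
    where diffusion is driven by graph Laplacians and each compartment
    may move on its own network layer. Provides generators for lattice,
    Erdos-Renyi and Barabasi-Albert topologies with per-edge compartment
    permissions, a positive-equilibrium solver for the model's cubic,
    Hurwitz stability checks, the Laplacian-eigenvalue dispersion relation
    and Turing interval for homogeneous networks, spectral-bound necessary
    conditions for Turing instability on heterogeneous three-layer
    networks, forward-Euler time integration with pattern-heterogeneity
    statistics, graph Fourier diagnostics of simulated patterns, and a
    random-walk least-squares calibration stage for cumulative adoption
    curves with intervention experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    methods,
    Rcpp,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
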