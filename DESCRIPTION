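Package: hubnet
Title: Lumped-Hub Analysis of Heterogeneous Boolean Threshold Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how outgoing hubs shape the dynamics of
    heterogeneous Boolean threshold networks. Generates directed network
    ensembles with scale-free out- or in-degree distributions, simulates
    asynchronous sign-threshold dynamics with frozen-core and quasi-fixed-point
    detection, reduces finite heterogeneous networks to a single effective
    ("lumped") hub coupled to a homogeneous bulk at three coarse-graining
    levels, and evaluates a damage-spreading mean-field theory that predicts a
    convergence/chaos phase transition as a function of hub strength, hub
    sparseness and bulk connectivity. Also provides exhaustive fixed-point
    enumeration for small dense networks with Poisson reference statistics,
    and trajectory statistics (participation ratio, autocorrelation decay)
    for non-converging dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    rlang,
    withr,
    generics,
    ggplot2,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
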