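Package: sentinet
Title: Sentinel Node Selection for Early Warning Signals on Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects sentinel node sets for anticipating tipping points in
    noisy dynamical systems on networks. Fluctuations around a stable
    equilibrium are modelled as a multivariate Ornstein-Uhlenbeck process
    whose stationary covariance solves a Lyapunov equation; the node-averaged
    sample variance is used as the early warning signal, and node sets are
    ranked by a separability statistic d between the signal distributions
    observed at two values of a bifurcation parameter. Includes closed-form
    two-node and three-node chain models, Euler-Maruyama simulation of four
    network dynamics models (coupled double-well, mutualistic interaction,
    gene regulatory, and SIS), network generators, baseline node selectors
    (Large SD, High/Low Input), and Kendall tau performance indices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
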