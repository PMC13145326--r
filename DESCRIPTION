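Package: modnest
Title: Modularity, Nestedness and Assembly Rules in Weighted Ecological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the structural analysis of weighted bipartite occurrence
    networks and food webs: weighted modularity (bipartite and directed
    unipartite objectives) optimized by simulated annealing with a restart
    policy, WNODA nestedness of whole matrices and same-module areas,
    connectance-preserving and module-constrained null models, module-level
    functional dispersion (FDis) and community-weighted means (CWM) tested
    against Monte Carlo null modules, trait and habitat/prey contingency
    tests, and abundance-degree regressions. Includes synthetic network and
    trait generators for planted-structure validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    cluster,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
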