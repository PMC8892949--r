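Package: cladescape
Title: Concordance-Factor Landscapes Across Clade Arrangements in Treespace
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping phylogenomic concordance across the full set of
    topological arrangements of major clades. Computes gene and site
    concordance factors per branch, re-evaluates them on every possible rooted
    arrangement of named clades, embeds the resulting landscape in treespace by
    Robinson-Foulds distance, performs quartet likelihood mapping and the SOWH
    parametric-bootstrap topology test under a Jukes-Cantor pruning likelihood,
    and fits Mk models with stochastic character mapping for discrete traits
    such as oviposition substrate. Includes multispecies-coalescent,
    sequence-evolution and Mk-trait simulators that generate complete test
    fixtures with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
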