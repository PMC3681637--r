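Package: matesim
Title: Two-Sex Demographic-Genetic Simulation of Mutation Accumulation
    under Mate Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic, individual-based simulation of a two-sex,
    age-structured population in which deleterious mutations with
    age-dependent onset accumulate under mutation-selection balance.
    Mating pairs form according to an age-indexed mating preference
    matrix, so male mate choice shapes the selection felt by female-
    and male-specific mortality and fertility mutations.  Includes
    Gompertz-Makeham life tables, configurable multi-locus genetics,
    preference-shift experiments, replicate summaries, and plotting of
    allele-frequency trajectories and end-state survivorship and
    fertility curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
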