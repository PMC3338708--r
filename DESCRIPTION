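Package: latticefold
Title: Lattice Go-Model Folding of Circular-Permutant Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the folding thermodynamics and kinetics of cubic-lattice
    Go-model proteins and of whole families of circular permutants derived from
    maximally compact parent structures. Provides Monte Carlo structure
    generation by homopolymer collapse, a local-move Metropolis engine with
    parallel tempering, heat-capacity and WHAM free-energy analysis over the
    energy coordinate, first-passage-time kinetics with single-exponential rate
    fits, Pfold-based transition-state-ensemble construction (contact order of
    the transition state, RMSD to native, transition-state networks), and
    family-level correlation reports relating folding rates to contact order.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
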