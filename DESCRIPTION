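Package: crowdmelt
Title: DNA Melting on Site-Diluted Lattices by Chain-Growth Monte Carlo
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the melting transition of a lattice Poland-Scheraga
    DNA model in a crowded medium modelled as quenched site dilution.
    Percolation disorder is grown with the Leath algorithm (depth-first or
    breadth-first), the two mutually avoiding strands are sampled with the
    pruned-enriched Rosenbluth method (PERM) including an optional pyramidal
    look-ahead bias with exact weight correction, and the package provides
    bubble-size statistics, annealed and quenched disorder averaging,
    finite-size data collapse for the melting temperature and crossover
    exponent, and exhaustive small-length enumeration as a ground-truth
    oracle. Monte Carlo inner loops are implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
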