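Package: ridgesim
Title: Forward-Time Evolution of Epistasis on Nonlinear Fitness Ridges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time Wright-Fisher simulation of diploid populations
    evolving on nonlinear genotype-phenotype landscapes under stabilizing
    selection, with developmental (per-individual) and environmental
    (population-wide, autocorrelated) phenotypic noise. Implements
    limiting-pathway and arbitrary ridge landscapes, an individual-level
    decomposition of case-control phenotype differences into heritable,
    additive and epistatic fractions, case-control sampling of extreme
    phenotypes, allele-lineage tracking, and effective-fitness /
    origin-fixation random-walk theory for corner localization of
    populations on fitness ridges.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
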