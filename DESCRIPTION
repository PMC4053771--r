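Package: dhrecomb
Title: Recombination Landscapes and Crossover Interference in Doubled-Haploid Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of meiotic recombination in doubled-haploid (DH) mapping
    populations genotyped with biallelic markers. Builds Haldane genetic maps on a
    fixed physical marker order, extracts crossovers from gamete genotypes, fits
    monotone Marey maps and derives recombination landscapes, compares genome-wide
    recombination rates and landscape shapes between populations, and estimates
    crossover interference under the two-pathway gamma-sprinkling model by maximum
    likelihood. Includes a meiosis simulator with known ground truth (stationary
    gamma renewal process for the interfering pathway, Poisson sprinkling for the
    non-interfering pathway) so every stage can be validated on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
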