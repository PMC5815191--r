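Package: irmsim
Title: Two-Locus Simulation of Insecticide Resistance Evolution Under
    Mixtures and Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic two-locus population-genetics simulation of the
    evolution of insecticide resistance in a randomly mating, sex-structured
    insect population. Genotype fitnesses are built from seven interpretable
    inputs per insecticide (effectiveness, exposure, resistance restoration,
    dominance of resistance, starting allele frequency, fitness cost and
    dominance of cost). The package runs single-insecticide, sequential and
    mixture deployment strategies, records time-to-resistance and linkage
    disequilibrium, compares strategies via the mixture/sequence ratio, and
    calibrates the fitness inputs from genotype-specific bioassay survival
    data. Includes a finite-population stochastic counterpart for checking
    the deterministic recursion, scenario presets, YAML scenario files, CSV
    trajectory output, ggplot2 visualisations and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
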