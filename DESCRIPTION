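Package: ecoscaffold
Title: Whole-Group Trait Altruism in Nutrient-Limited Microbial Metapopulations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic birth-death-mutation simulation of altruistic
    (public-good producing) and selfish microbial cell types competing for a
    limited nutrient influx, within single well-mixed groups and across a grid
    metapopulation with episodic dispersal by random migration, selective
    migration, or trait-group pooling and redistribution. Provides closed-form
    calculators for the hard- and soft-selection fitness structures, the
    strong versus weak altruism classification, migration mixing proportions,
    group transition rates, and the multilevel (MLS1) Price decomposition,
    together with seeded Monte Carlo experiment drivers for fixation
    probability estimation with binomial confidence intervals and an exact
    absorbing-Markov-chain solver for small systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
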