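Package: harvestcascade
Title: Individual-Based Eco-Evolutionary Simulation of Harvested Food Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic individual-based simulation of three- and four-level
    food chains in which non-harvested trophic levels evolve a quantitative
    trait along a competition-defense tradeoff. Consumption follows a Holling
    type II functional response; births are Poisson, deaths binomial; harvest
    adds consistent-effort mortality at the top or penultimate level.
    Experiments bifurcate into eco-evolutionary and ecology-only (genotypes
    frozen) branches at harvest onset to isolate the effect of non-target
    evolution on harvested-species abundance, yield and sustainability.
    Includes scenario presets, harvest-intensity and tradeoff-ratio sweeps,
    generation-time and realized-heritability metrics, yield curves with
    maximum-sustainable-yield estimates, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
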