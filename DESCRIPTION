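Package: revegrowth
Title: Neighborhood and Trait Drivers of Plant Growth in Mixed-Species
    Restoration Plantings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse individual plant relative growth rate in
    mixed-species revegetation plantings. Converts stem diameters to
    aboveground biomass through pluggable allometric equations, computes
    neighborhood density and diversity predictors (rarefied species
    richness, functional evenness and dispersion from species-mean
    traits), builds a seven-model ladder of linear mixed models with
    crossed spatial and species random intercepts, genus-specific slopes
    and moisture-availability interactions, and establishes permutation
    null distributions for standardized partial regression slopes by
    shuffling growth rates across focal plants. Includes a synthetic-data
    generator that emulates the nested planting/plot/plant sampling
    design with known ground-truth coefficients, so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
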