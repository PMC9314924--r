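Package: camosim
Title: Simulated Camouflage Evolution with a Real-Coded Genetic Algorithm
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A headless toolbox for artificial camouflage evolution
    experiments. A tailored real-coded genetic algorithm with tagged decimal
    genes (overdispersed initialization, incomplete weighted-average
    crossover, Poisson point mutation, tag-aware swap/scramble/duplication
    mutations, elitist lifelines and adaptive mutation rates) drives
    procedural animal and egg phenotypes - Gray-Scott reaction-diffusion
    maculation, CIELAB coloration, edge enhancement, speckling, and a
    two-axis (deposition x biliverdin:protoporphyrin) egg pigment model -
    through simulated visual-search predation against photographic or
    synthetic backgrounds. Camouflage is quantified by CIELAB mean and
    standard-deviation differences from the local background and by the
    GabRat Gabor edge-disruption metric.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
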