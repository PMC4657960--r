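Package: radflux
Title: Generalized Radiation Models for Human Mobility Fluxes
Version: 0.1.0
Authors@R: person("radflux", "developers", email = "radflux@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling origin-destination trip matrices with the
    radiation model of human mobility and its singly-constrained
    generalizations. Provides the intervention-based and competition-based
    kernels, production- and attraction-constrained variants (PIR, PCR, AIR,
    ACR) with a scaling exponent lambda and a normalization factor kappa,
    grid-search fitting by Sorensen-Dice flux similarity, a validation battery
    (trip-distance and trip-population distributions, Kolmogorov-Smirnov
    tests, binned flux coverage, phase-space error grids), a synthetic
    mobility-system generator for end-to-end testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
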