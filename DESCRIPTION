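Package: chemopt
Title: Optimal Chemotherapy Scheduling Under Drug-Induced Resistance
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and optimal-control analysis of a two-compartment
    (drug-sensitive / drug-resistant) tumor model in which chemotherapy both
    kills sensitive cells and induces transitions to the resistant phenotype.
    The package maximizes the time the total tumor burden stays below a
    critical volume, synthesizing the optimal structure of bang-bang arcs plus
    a boundary (sliding) feedback dose. It provides the Lie-bracket phase-plane
    geometry (singular line, tangency point, Legendre-Clebsch diagnostics),
    Pontryagin Maximum Principle verification of candidate controls, clock-form
    time identities, structural-identifiability recovery of model parameters
    from volume-output Lie derivatives, and a command-line interface
    reproducing the quantitative experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
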