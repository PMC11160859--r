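Package: genfilter
Title: Simulation and Exact Likelihood for Structured Markov Genealogy Processes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phylodynamic likelihood computation under discretely
    structured Markovian population models. A population model is specified as
    a set of marked jump types (births, deaths, migrations, sampling, neutral
    and compound events) acting on a finite lattice of population states, each
    jump mark carrying a fixed per-deme production of emergent lineages.
    The package simulates the population process together with the genealogy
    it induces, prunes genealogies down to their sample-spanning subtree,
    obscures deme information, and computes the exact likelihood of pruned and
    obscured genealogies by solving the associated filter equations (forward
    and adjoint), by closed-form expressions for the Kingman coalescent with
    serial sampling and for the linear birth-death-sampling process, and by a
    sequential Monte Carlo estimator for models whose deterministic filter is
    intractable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
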