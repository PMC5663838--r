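Package: maxepp
Title: Entropy-Production State Selection in Bistable Chemical Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how entropy production selects among coexisting
    nonequilibrium steady states in the bistable Schloegl reaction network.
    Provides the macroscopic rate equations and their entropy production, exact
    stationary and time-dependent solutions of the chemical master equation on
    the underlying birth-death chain together with entropy flow and production
    rates, state weights split at the separatrix, the critical driving strength
    of the first-order nonequilibrium phase transition, mean first-passage
    times, the large-volume (WKB) nonequilibrium potential with Gaussian-peak
    and escape-rate asymptotics, an exact Gillespie simulator with per-jump
    medium entropy and fluctuation-theorem checks, and a flux-constrained
    Langevin model with its Onsager-Machlup action decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
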