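Package: barebones
Title: Stochastic Dynamics of Mutant Establishment in the Bare Bones Evolution Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact stochastic simulation and limit theory for a two-type
    binary-splitting population model with carrying capacity K, in which a
    critical resident population is invaded by an initially advantageous
    mutant. Provides the deterministic density map with its four fixed points
    and their stability, the scaling-limit function H obtained by iterating
    the map along the unstable direction (a two-dimensional Abel functional
    equation), the one-dimensional Schroeder conjugacy used to bound the
    iterates, coupled Galton-Watson approximations driven by shared uniform
    variates, exit times from the tube around the resident equilibrium, the
    martingale limit W of the mutant lineage, and the establishment time
    [log K / log rho] and probability 2(1 - 1/rho) of the mutant, with
    Monte Carlo tools to compare the finite-K process against the
    deterministic flow started from its random initial condition.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
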