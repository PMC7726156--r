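Package: pebridge
Title: Monte Carlo Simulation of Ion-Mediated Interactions Between
    Like-Charged Polyelectrolytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Coarse-grained Metropolis Monte Carlo simulator for two
    like-charged, bendable polyelectrolyte chains in mixed monovalent and
    trivalent salt. Chains are discrete worm-like bead chains with fixed
    bond length; non-bonded interactions are bare Coulomb under the
    minimum-image convention plus a purely repulsive truncated
    Lennard-Jones (WCA) excluded volume. The engine supports parallel
    rigid, rotatable rigid and bendable chains, optional cylindrical
    confinement modelling a hexagonal polyelectrolyte array, mean-force
    accumulation with a force-symmetry equilibration criterion,
    integration of the mean force into potentials of mean force, and
    structural observables: cumulative ion charge fraction profiles,
    effective chain-chain separation, and multivalent bridging-ion
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
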