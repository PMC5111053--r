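Package: polylat
Title: Dynamic Monte Carlo Simulation of Lattice Polymers at Adsorbing
    Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Single-chain dynamic Monte Carlo simulation of a coarse-grained
    fluctuating-bond polymer on the simple cubic lattice, in bulk solution,
    near an attractive impenetrable surface, and strictly confined to two
    dimensions.  Implements Metropolis single-monomer dynamics with
    self-avoidance, bond-length and bond-crossing constraints, intra-polymer
    nearest-neighbour attraction and polymer-surface attraction.  Provides
    estimators for the parallel translational diffusion coefficient from the
    centre-of-mass mean-square displacement, the rotational relaxation time
    from the end-to-end vector autocorrelation function, chain-length scaling
    exponents, and a coil-globule transition locator, together with an exact
    enumeration oracle for validating equilibrium sampling of short chains.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
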