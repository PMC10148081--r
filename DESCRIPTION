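Package: pccsort
Title: Oligomeric Isomer Enumeration and Assembly Equilibrium Analysis
    for Partially Occupied Multienzyme Particles
Version: 0.1.0
Authors@R:
    person("pkg", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing compositional heterogeneity of a
    D3-symmetric alpha6-beta6 multienzyme complex (propionyl-CoA
    carboxylase) from symmetry-expanded cryoEM particle metadata.
    Enumerates binding-site occupancy configurations and their orbits
    under the point group (oligomeric isomers and formulae), implements
    the particle sorting method that assigns each particle an oligomeric
    formula by counting alpha-missing focused-classification labels,
    estimates stepwise association attributes Kc[alpha] and their
    exponential decay, and ships a synthetic particle generator plus a
    minimal STAR-dialect reader/writer and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
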