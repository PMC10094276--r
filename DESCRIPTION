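Package: brinesim
Title: Mass-Transfer Kinetics and NaCl Diffusion Simulation for Brine Curing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing salt and water exchange during wet curing of
    muscle tissue slabs. Implements phase-composition arithmetic for the
    aqueous-phase NaCl content, square-root-of-time mass-transfer kinetic
    fits, linear/power/exponential time-variant concentration models,
    effective-diffusivity estimation by the slope method and by inversion of
    the semi-infinite erf profile, a Crank-Nicolson finite-difference solver
    for transient Fickian diffusion in 1D and 3D slabs with Dirichlet and
    no-flux boundaries, and a synthetic-data generator that emulates a
    xylitol-mediated pork-curing experiment from known ground-truth
    parameters. An end-to-end pipeline runs generation, fitting, diffusivity
    estimation, simulation and profile validation from one configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
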