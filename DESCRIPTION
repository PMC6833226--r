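Package: spindlemag
Title: Static Magnetic Field Perturbation of Mitotic Spindle Positioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanical model of how a strong static magnetic field (SMF)
    perturbs microtubules and thereby slows mitotic spindle positioning and
    orientation in large embryonic blastomeres. Provides closed-form
    magneto-physics for tubulin dimers and microtubules (magnetic torque,
    Boltzmann orientation distribution, direction-dependent polymerization
    rate, rotation rate, Euler-Bernoulli deflection under a distributed
    magnetic torque, and the chord-projected reduction of the pulling
    force), a seeded Monte Carlo simulator of spindle positioning and
    orientation in an elliptical cell driven by astral-microtubule forces,
    relaxation-time extraction from trajectories, and an accumulator that
    converts per-cycle slowdown over the early cleavage schedule into a
    whole-embryo developmental delay estimate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
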