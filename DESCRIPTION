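Package: gestag
Title: Kinetic Modelling of Plasma 1,5-Anhydroglucitol During Pregnancy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-compartment mass-balance model of plasma
    1,5-anhydroglucitol (1,5-AG) across gestation, for normal and
    diabetic (GDM/DM) pregnancy. Provides the gestational physiology
    curves (quadratic glomerular filtration rate, sigmoidal plasma
    volume, linear fractional plasma mass) and their least-squares
    fitting; a glucose- and gestation-dependent renal reabsorption
    model; closed-form and ODE-integrated steady-state 1,5-AG
    trajectories; one-at-a-time parameter sweeps; simplex calibration
    of model variants to longitudinal group-mean 1,5-AG data; and
    seeded synthetic-cohort generators for parameter-recovery studies.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
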