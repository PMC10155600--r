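Package: rheomqf
Title: Multiple-Quantum-Filtered Sodium Rheo-NMR and Bulk Rheology of
    Biopolymer Fluids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward models and sequential constrained fitting of spin-3/2
    sodium-23 double-quantum-filtered magic-angle (DQF-MA) and
    triple-quantum-filtered (TQF) build-up curves, with signal-to-noise-based
    uncertainty propagation, shear-rate and temperature series analyses
    (linear shear dependence of the residual quadrupolar coupling, Arrhenius
    behaviour of relaxation times), and the companion bulk-rheology workflow:
    Herschel-Bulkley / power-law / Newtonian constitutive fitting with a
    replicate-dispersion model-selection cascade, linear-viscoelastic-region
    detection, storage/loss modulus crossover, and Cox-Merz comparison.
    Includes seeded synthetic-data generators that emulate a sheared dilute
    kappa-carrageenan fluid across its helix-coil transition, so the whole
    analysis is reproducible without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
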