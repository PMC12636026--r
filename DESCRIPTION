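Package: coilrelax
Title: Relaxometry and Stability Analytics for Lanthanide-Binding Coiled Coils
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis toolkit for lanthanide(III) coiled-coil
    MRI contrast agents. Implements a second-sphere plus outer-sphere
    model of the longitudinal water-proton relaxivity dispersion (Solomon-
    Bloembergen-Morgan dipolar term with Lipari-Szabo model-free spectral
    densities and transient zero-field-splitting electron-spin relaxation,
    plus the Freed outer-sphere model), weighted least-squares fitting of
    NMRD profiles with multi-start and bootstrap uncertainties, equilibrium
    speciation and affinity inference from direct (Hill) and EGTA-competition
    luminescence titrations, kinetic-stability ratio indices, circular-
    dichroism helicity estimates, tryptic fragment prediction with
    cross-link resistance, hydration-shell trajectory statistics (radial
    distribution functions, shell occupancy, residence lifetimes), and
    seeded synthetic-data generators so every analysis stage can be
    exercised offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
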