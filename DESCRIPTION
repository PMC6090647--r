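Package: propiokin
Title: Kinetic Modelling of Propionic Acid Batch and Fed-Batch Fermentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Non-structured kinetic model of propionic acid production by
    Propionibacterium acidipropionici: Monod substrate uptake with propionic
    and acetic acid product inhibition, Luedeking-Piret product formation for
    propionic, pyruvic, acetic and succinic acid, and fed-batch dilution
    dynamics. Provides ODE simulation of batch and fed-batch cultures,
    nonlinear least-squares parameter estimation with a per-variable averaged
    coefficient of determination, constant-rate feeding-strategy design under
    a sugar-accumulation constraint, fermentation performance metrics (yield,
    volumetric productivity, acid ratios, specific rates), ratiometric BCECF
    intracellular pH calibration, and seeded synthetic-data generators for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
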