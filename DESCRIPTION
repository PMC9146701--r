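Package: emulsionrheo
Title: Local Flow Curves, Yield-Stress Kinetics and NMR Droplet Sizing
    for Concentrated Emulsions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for time-dependent yield-stress decay in
    concentrated oil-in-water emulsions characterized by rheo-MRI and
    low-field NMR.  Reconstructs local flow curves from Couette-cell
    velocity profiles and torque, fits the Herschel-Bulkley law with a
    global flow index across a shear-time series, models yield-stress
    breakdown with second-order structural kinetics, sizes emulsion
    droplets from pulsed-field-gradient diffusion decays through the
    Murday-Cotts restricted-diffusion model, and computes 2D D-T2
    correlation maps by regularized non-negative inverse Laplace
    inversion.  A seeded synthetic-data generator forward-simulates
    every measurement so the full pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    pracma,
    rlang,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
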