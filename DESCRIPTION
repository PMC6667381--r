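Package: rostrack
Title: Quantification of Radiation-Induced Reactive Oxygen Species from
    EPR Spin-Trapping Data
Version: 0.1.0
Authors@R:
    person("rostrack", "developers", email = "rostrack@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for electron paramagnetic resonance (EPR)
    spin-trapping dosimetry of water radiolysis products. Fits the
    three-phase DMPO-OH vs spin-trap density titration curve to separate
    sparse and dense localized hydroxyl-radical generation, converts
    between molar concentration, linear trap density and inter-radical
    spacing via the cube-root rule, corrects measured adduct
    concentrations for first-order decay during and after irradiation,
    quantifies hydrogen peroxide through linear calibration curves with
    inverse prediction, assembles LET-dependent per-Gy oxidation budgets
    with the hydroxyl/hydroperoxyl partition of total oxidation, and
    standardizes per-Gy yields into depth profiles. Includes synthetic
    generators for every input so the full pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
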