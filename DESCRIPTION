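Package: neurovasc
Title: Microvascular Bolus Tracking, Theta-Gamma Coupling and Vascular
    Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis chain for neurovascular dysfunction
    studies: gamma-variate modeling of two-photon line-scan bolus
    passages with time-to-peak extraction, estimation of hypercapnia-induced
    network flow change from paired time-to-peak dispersion via orthogonal
    (Deming) regression with hierarchical bootstrap uncertainty,
    theta-gamma phase-amplitude coupling analysis of local field
    potentials (Canolty modulation index, circular-shift surrogate null,
    Bonferroni-corrected comodulograms), and pixel-ratio morphometry of
    immunofluorescence masks (mural-cell coverage and detachment, plaque
    load, vascular amyloid load). Includes seeded synthetic-data
    generators with known ground truth for bolus cohorts, coupled local
    field potentials, and labeled mask scenes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
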