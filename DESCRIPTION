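Package: gelstrain
Title: Viscoelastic Gel-Point Design and Left-Ventricular Segmental Strain
    Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for designing heart-rate-matched viscoelastic hydrogel
    patches and for quantifying regional left-ventricular mechanics from
    short-axis wall contours.  Implements generalized Maxwell (Prony
    series) linear viscoelasticity: storage and loss moduli, gel-point
    (G' = G'') extraction from oscillatory frequency sweeps,
    multi-exponential stress-relaxation fitting, and
    Boltzmann-superposition stress simulation under arbitrary strain
    histories.  A calibration layer maps hydrogel recipes (gelatin weight
    fraction and fluorinated:plain phenylboronic acid crosslinker ratio)
    to gel points and selects formulations matched to a species' heart
    rate and myocardial stiffness.  A strain module computes 24-segment
    circumferential strain and adjacent-segment strain differentials from
    cine wall contours, locating the infarct border as the site of the
    maximum strain gradient.  Seeded synthetic generators provide
    rheometer sweeps, relaxation curves, and beating-ventricle contour
    phantoms with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
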