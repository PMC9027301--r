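Package: ecisbarrier
Title: Impedance-Based Endothelial Barrier Analysis with Rb/Alpha/Cm Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing electric cell-substrate impedance sensing
    (ECIS) experiments on endothelial monolayers. Implements the
    Giaever-Keese cell-covered-electrode model with a constant-phase-element
    electrode interface, per-timepoint deconvolution of multifrequency
    impedance spectra into paracellular resistance (Rb), cell-substrate
    constraint (alpha) and membrane capacitance (Cm), frequency-selection and
    normalised-timecourse analysis with area-under-curve statistics, Seahorse
    Mito-Stress oxygen-consumption metrics and LDH cytotoxicity, and a seeded
    synthetic-experiment generator emulating a CoCl2 dose-response study on
    human retinal endothelial cells.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
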