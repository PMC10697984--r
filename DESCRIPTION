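Package: penumbralet
Title: Restricted LET and RBE Outside Small Megavoltage Photon Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising radiation quality outside the edges of
    small 6 MV photon radiotherapy fields. Provides closed-form restricted and
    unrestricted electron collision stopping powers in liquid water
    (Moller/Bethe with Sternheimer density-effect correction), track-average
    and dose-average restricted LET moments of binned electron fluence spectra
    with a track-end correction at the delta-ray cutoff, a quadratic
    calibration of maximum low-dose RBE against photon energy for the
    dicentric endpoint, and a deterministic synthetic generator of 6 MV-like
    photon spectra and their electron slowing-down fluences (total and
    secondary-electron-only) across field size, water depth and off-axis
    distance. Ships a transcription of published LET/RBE tables for the same
    geometries and summary statistics over them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
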