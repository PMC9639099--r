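Package: adsorient
Title: Orientation Ensembles of Redox Enzymes on Planar Electrodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the electrostatic adsorption of a redox enzyme on a planar
    conducting electrode as a Boltzmann ensemble of rigid-body orientations.
    Reads point-charge structures (PQR), samples tilt/azimuth orientation
    grids, evaluates per-orientation protein-electrode interaction energies
    with a screened-Coulomb image-charge half-space model (or ingests external
    per-orientation energy tables), converts energies to orientation
    probabilities and Langmuir adsorption constants, and predicts
    electron-transfer-weighted electrode currents via exponential
    distance-decay rates. Includes seeded synthetic-fixture generators for
    desk-scale testing, surface-patch diagnostics (nearest residue, patch
    charge), and ggplot2 visualisations of orientation landscapes and
    current-pressure isotherms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
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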