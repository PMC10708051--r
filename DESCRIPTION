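Package: ctcassay
Title: Charge-Transfer Complex Spectrophotometry and Microwell Assay Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing charge-transfer complexes (CTCs) of an
    electron-donor drug with pi-acceptors from UV-visible absorption data:
    band-maximum detection, Benesi-Hildebrand association-constant fitting,
    Tauc-plot band-gap extraction, Job's continuous-variation stoichiometry,
    derived electronic constants (ionization potential, standard free energy,
    oscillator strength, transition dipole, resonance energy), and
    partial-charge donor-site ranking. Includes ICH-style microwell assay
    validation (calibration, LOD/LOQ, precision/accuracy, recovery, label
    claim, throughput), an Analytical Eco-Scale greenness calculator, and a
    synthetic-data module that emulates Beer-Lambert Gaussian-band spectra,
    exact 1:1 complexation equilibria, direct-transition absorption edges and
    heteroscedastic 96-well calibration plates so every stage is testable
    without instrument data.
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
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
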