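Package: tptcr
Title: Targeted Proton Transfer Charge Reduction Mass Spectrometry Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation, detection, deconvolution and spatial imaging of
    intact non-covalent protein-ligand complexes from low-resolution,
    charge-reduced native mass spectrometry data. Provides exact
    charge-state arithmetic, a seeded synthetic-data generator for native
    electrospray spectra (full-scan, selected ion monitoring, proton
    transfer charge reduction and collision-induced neutral-loss scans)
    and tissue-phantom imaging datasets, charge-ladder intact-mass
    deconvolution, targeted product-ion image generation with region
    statistics, neutral-loss ligand assignment, and a minimal top-down
    b/y fragment matcher. Reads and writes mzML, a continuous-mode imzML
    dialect, CSV target tables and PNG ion images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    readr,
    xml2,
    png,
    generics,
    mzR,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
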