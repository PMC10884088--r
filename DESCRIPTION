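Package: rootcalib
Title: Inverse Identification of Aortic Root Material Parameters from
    Two-Phase Imaging Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-invasive calibration of linear-elastic material parameters
    for the aortic root wall and stenotic valve leaflets of transcatheter
    aortic valve implantation (TAVI) patients. Fits a quadratic
    response-surface surrogate to forward-model evaluations sampled over a
    design of experiments, solves the resulting cost functions for the
    patient-specific Young's modulus, and verifies the solution by
    re-running the forward model. Ships a pluggable forward-model contract
    with a Laplace-law reference wall model and a simplified leaflet-opening
    model, the image-derived observables used for calibration and validation
    (diameter strain, spline orifice area, voxel Jaccard index, stent frame
    diameters), a catalog of the constitutive laws and parameters used in
    device simulation, and a seeded virtual-patient cohort generator for
    parameter-recovery experiments.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lhs,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
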