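Package: lungstretch
Title: Pressure-Based Stretch Monitoring and Aerosol Dosimetry for
    Breathing Lung Bioreactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for cell-stretch lung bioreactors in which a
    circular elastic membrane carrying an air-liquid-interface epithelial
    culture is cyclically bulged by positive apical pressure. Converts dual
    pressure-sensor traces into membrane deflection, linear and area strain,
    stretch frequency and the membrane's triaxial Young's modulus via a
    spherical-cap bulge-test model; estimates membrane porosity from
    gravimetric liquid-displacement data and from polymer composition;
    performs aerosol dosimetry bookkeeping (deposited mass and particle
    surface-area dose); quantifies transepithelial particle translocation
    from basal-medium fluorescence with standard-curve calibration and
    limit-of-detection handling; maps breathing physiology (tidal volume,
    functional residual capacity) to alveolar strain; and ships a synthetic
    instrument-data generator so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
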