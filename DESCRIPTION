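Package: etis
Title: Equivalent Temperature Index for Sows and Companion Thermal Indices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the equivalent temperature index for sows (ETIS), a
    heat-stress score for group-housed sows that augments dry-bulb air
    temperature with equivalent-temperature corrections for relative
    humidity, air velocity (convection), floor heat conduction and
    long-wave radiation.  Provides the psychrometric conversions
    (saturation vapor pressure, dew point, wet bulb) needed by classical
    comparison indices (eight temperature-humidity index variants, the
    black-globe humidity index, effective temperature and moist-air
    enthalpy), a rank-deficient least-squares calibration pipeline that
    fits the index coefficients against skin temperature, a THI-anchored
    heat-stress threshold classifier, and a moment-matched synthetic barn
    data generator for end-to-end testing without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse, yaml
Config/testthat/edition: 3
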