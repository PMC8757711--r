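Package: venaloop
Title: Digital Twin of a Venous Mock Circulatory Loop for Catheterization Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a bench-top venous mock circulatory loop of the kind
    used to train cardiac catheterization and to test pulmonary-artery
    catheters. Synthesizes pulsatile superior/inferior vena cava flow
    waveforms, combines them through split-tube continuity into the pump
    inflow profile, computes Poiseuille wall shear stress and shear rate,
    models the loop's PWM-driven impeller pump with bucket-test calibration
    and an affine flow correction, simulates Hall-effect turbine flow
    sensors and a thermostat-controlled heated reservoir, and verifies the
    as-built heart and vessel dimensions against literature ranges. A
    configuration-driven validation report reproduces the loop's full
    verification battery.
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
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
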