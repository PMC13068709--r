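Package: rfetsense
Title: Multiscale Response Modeling of Reconfigurable Field-Effect
    Transistor Biosensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the electrical response of dual-gate Schottky-barrier
    reconfigurable field-effect transistor (RFET) biosensors from molecular
    binding parameters. Couples single-site Langmuir binding thermodynamics
    and Debye-screened probe-layer electrostatics with a two-dimensional
    drift-diffusion device simulator (Scharfetter-Gummel discretization,
    Tsu-Esaki thermionic/tunneling Schottky injection) to compute
    dual-polarity transfer characteristics, calibration curves, and relative
    current responses for aptamer- and enzyme-functionalized sensors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
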