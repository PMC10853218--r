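Package: nightbrace
Title: Automated Design of Nighttime Scoliosis Braces by Patient-Specific
    Simulation and Surrogate Shape Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated design of patient-specific nighttime braces for
    adolescent idiopathic scoliosis. Generates parametric synthetic scoliotic
    trunk anatomies, builds a reduced-order static finite-element model of the
    trunk (beam-element spine, soft-tissue springs, penalty contact), derives an
    over-corrected initial brace by sagittal-plane mirroring of the vertebral
    pedicles, and optimizes the brace surface topography over a cylindrical
    6 x 6 patch grid with a radial-basis-function surrogate optimizer. Brace
    effectiveness is scored from simulated in-brace correction and a two-year
    growth-modulated outcome following the Hueter-Volkmann stress-growth law,
    under a skin contact-pressure safety constraint.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
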