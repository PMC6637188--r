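Package: hotparticle
Title: Microdosimetry and DNA Damage Kinetics Around a Radioactive
    Cs-Bearing Microparticle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative chain from a single insoluble Cs-bearing
    radioactive microparticle to spatially resolved DNA double-strand-break
    burden in a cell monolayer. Computes the radial beta/gamma absorbed
    dose-rate field around the particle (straight-ahead CSDA electron Monte
    Carlo through layered materials plus an analytic photon point kernel
    with buildup), models cumulative gamma-H2AX focus induction competing
    with first-order repair, generates synthetic cell populations and
    two-channel fluorescence focus images with ground truth, counts foci by
    nucleus segmentation and spot detection, and compares exposure groups
    with the Tukey-Kramer multiple-comparison test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
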