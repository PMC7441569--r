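Package: pvsflow
Title: Paravascular CSF Flow, Brain Tissue Coupling, and Two-Photon
    Displacement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Axisymmetric finite-element simulation of cerebrospinal fluid
    movement in the paravascular space (PVS) surrounding penetrating
    arterioles. The PVS fluid is modeled with the incompressible
    Darcy-Brinkman equations (recovering Navier-Stokes at infinite
    permeability), the surrounding brain tissue as a compressible Saint
    Venant-Kirchhoff solid, and the two are coupled through a monolithic
    arbitrary Lagrangian-Eulerian fluid-structure interaction scheme with
    lumped Robin flow resistances at the subarachnoid and parenchymal ends.
    Post-processing computes boundary fluxes, volume exchange fractions,
    Reynolds and Peclet numbers, frequency power laws and Lagrangian particle
    trajectories. The package also implements a two-photon image-analysis
    pipeline (subpixel DFT registration, channel crosstalk unmixing,
    Radon-space vessel diameter, piecewise tissue-displacement estimation
    with acceptance gating, and impulse-response summarization) together
    with a synthetic two-channel movie generator used to validate it.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    matrixStats,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    tiff
Config/testthat/edition: 3
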