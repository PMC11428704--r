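Package: hemoflow
Title: Pulsatile Hemodynamics and Wall Shear Stress Indices in Synthetic Vessels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational hemodynamics for aortic aneurysm and
    dissection studies. Generates synthetic two-dimensional vessel domains
    (straight tubes, dissected two-lumen channels), solves transient
    incompressible generalized-Newtonian flow with Carreau-Yasuda blood
    rheology on structured staggered grids, and post-processes wall shear
    stress into the four endothelial risk indices: time-averaged wall shear
    stress (TAWSS), oscillatory shear index (OSI), relative residence time
    (RRT) and endothelial cell activation potential (ECAP). Includes
    parameterized physiological pressure and velocity pulse synthesis,
    Womersley and Poiseuille analytic oracles, waveform comparison metrics
    for true/false-lumen analysis, and synthetic fixture generators with
    known ground truth.
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
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
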