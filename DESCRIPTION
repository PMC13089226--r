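Package: plesiomass
Title: Skeletal Reconstruction and Volumetric Body-Mass Estimation for
    Plesiosaurs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating body mass in plesiosaurs (Mesozoic marine
    reptiles) from skeletal measurements. Reconstructs ribcage transverse
    cross-sections from dorsal rib orientation angles, assembles a body axis
    with intervertebral cartilage and trunk spinal curvature, integrates body
    volume with the cross-sectional method (slab integration with linear
    shape transitions), and converts volume to mass at seawater density.
    Includes an allometric regression suite (ordinary least squares,
    phylogenetic generalized least squares under Brownian motion,
    four-parameter log-logistic fits, AICc, leave-one-out percent prediction
    error), minimum-branch-length time calibration of fossil phylogenies,
    published missing-element and body-mass equations as ready-to-use
    predictors, and seeded synthetic-data generators for every pipeline
    input.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
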