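Package: valveflow
Title: Wall Shear Stress and Fluorescence Quantification for Embryonic Heart Valve Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates wall shear rate and wall shear stress at the
    atrioventricular canal of the embryonic zebrafish heart from beating-heart
    microscopy, under a two-phase blood model (tracked red blood cells and a
    linear near-wall flow profile) and a one-phase plasma model (ventricular
    volume traces, parabolic flow through the maximum inscribed circle of the
    lumen cross-section).  Includes the Corcione effective-viscosity
    correlation for nanoparticle-laden plasma with an injection-dilution
    calculator, free-form-deformation image registration for particle
    tracking, intensity-budget quantification of single-molecule FISH dot
    densities with background correction, junction and apical-basal polarity
    intensity ratiometry, and seeded synthetic-data generators with analytic
    ground truth for validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    pracma,
    Matrix,
    tiff,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
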