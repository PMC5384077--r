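Package: conjflow
Title: Conjunctival Microvascular Hemodynamics from Image Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying microvascular hemodynamics
    in one-second image sequences of the bulbar conjunctiva: frame quality
    screening and translational registration, Frangi-filter vessel
    segmentation with centerline extraction and bifurcation splitting,
    full-width-at-half-maximum diametry, spatio-temporal image (kymograph)
    velocimetry, and derived descriptors (cross-sectional velocity, blood
    flow, wall shear rate, diameter-dependent blood viscosity, wall shear
    stress). Includes group-level statistics (ANOVA and random-intercept
    linear mixed models with covariate adjustment, velocity-diameter slopes)
    and a synthetic-sequence and synthetic-cohort generator with known ground
    truth so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    lme4,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
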