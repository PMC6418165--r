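Package: coartkin
Title: Coarticulation Analysis of Sequential Planar Hand Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinematic analysis of sequential planar hand movements through
    ordered targets, as recorded with a stylus tablet. Provides trajectory
    smoothing with fixed-knot regression splines, tangential-velocity
    segmentation with relative thresholds, a trough-to-peak coarticulation
    score with inflection-point substitution for merged submovements,
    path-offset and spatial-error measures, a minimum-jerk submovement
    superposition simulator with via-point optimization that maps submovement
    overlap to the predicted score and curvature, a synthetic cohort generator
    with ground-truth learning dynamics, and the mixed-design ANOVA and
    non-parametric statistical battery used to compare training groups across
    sessions, blocks and transfer conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    broom,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
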