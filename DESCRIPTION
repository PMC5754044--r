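Package: npcohort
Title: Nutrient Profile Scoring and Cohort Survival Analysis for
    Less-Healthy Food Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Implements the UK FSA-Ofcom nutrient profiling model
    (per-100-g component points, the A-point protein gate, and the
    food/beverage less-healthy classification), builds person-level
    less-healthy food exposures from 7-day diet diaries, applies
    cohort exclusion rules (diary completeness, Schofield-equation
    energy misreporting trims, prevalent disease, missing covariates),
    and fits Cox proportional-hazards models over exposure quintiles
    with trend tests, isocaloric substitution models, and Schoenfeld
    residual diagnostics. A synthetic-study generator emulating the
    confounding structure of a UK population-based cohort makes the
    whole chain testable end to end.
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
    survival,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
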