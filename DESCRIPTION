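Package: diabtraj
Title: Diabetes Subtype Classification and Biomarker Trajectory Modelling
    for Longitudinal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying health-parameter trajectories around the
    diagnosis of type 2 diabetes in longitudinal cohort studies. Implements
    nearest-centroid classification into the novel diabetes subtypes (SIDD,
    SIRD, MOD, MARD, with GADA-positive individuals gated to SAID), including
    a fasting-glucose variant of the centroid scheme, HOMA beta-cell and
    insulin-resistance indices with explicit unit handling, a diagnosis-anchored
    relative timeline, an auditable eligibility and exclusion cascade,
    multilevel mixed-effects trajectory models with estimated marginal means
    and pairwise subtype contrasts, and a seeded synthetic-cohort generator
    emulating a three-exam prevention-programme design so the full pipeline is
    testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    lme4,
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
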