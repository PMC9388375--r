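Package: cvdproj
Title: Population Projection of Cardiovascular Disease Under Blood Pressure
    Intervention Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects country-level cardiovascular disease (CVD) burden to
    mid-century by embedding four-state Markov models for ischemic heart
    disease, hypertensive heart disease, ischemic stroke and hemorrhagic
    stroke within a cohort-component demographic projection. Systolic blood
    pressure distributions are modelled as discretized normals; dietary
    sodium reduction and hypertension-treatment scale-up scenarios shift
    these distributions, and relative-risk weighting converts the shifts
    into changes in disease incidence and case fatality. Includes a
    synthetic country-data generator, calibration of transition
    probabilities to target prevalence and mortality series, life-table
    summary measures (including the probability of dying from CVD between
    ages 30 and 80), and a demographic decomposition of projected change
    into growth, aging and rate components.
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
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
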