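Package: nutricea
Title: Cost-Effectiveness Modelling of Nutrition Supplementation for Adults Starting Antiretroviral Therapy
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markov cohort cost-effectiveness analysis of adding short-course
    macronutrient supplementation to antiretroviral therapy (ART) for
    malnourished HIV-infected adults. Derives BMI-stratified quarterly
    transition probabilities (alive/active, dead, lost to follow-up) from
    cohort disposition tables, evaluates a two-cycle three-state Markov model
    of per-patient cost and DALYs averted, computes willingness-to-pay
    benchmarks for ART alone, and solves the maximum quarterly supplement
    price that preserves cost-effectiveness parity. Includes retention
    surfaces and parity frontiers, one-way sensitivity analyses over ART
    programme cost and return-to-care of patients lost to follow-up,
    commodity-based supplement ration costing, a multinomial synthetic-cohort
    generator for parameter-recovery experiments, and report writers with a
    thin command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
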