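Package: renalmeal
Title: Simulation and Concordance Scoring for Hemodialysis Meal-Plan
    Evaluation
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools to evaluate machine-generated single-day meal plans for
    patients on maintenance hemodialysis. Simulates guideline-concordant
    hypothetical patient cohorts with individualized nutrition goals
    (truncated log-normal mineral maxima, weight-scaled calorie and
    protein targets), renders standardized meal-planning prompts,
    synthesizes structured meal-plan responses with controllable
    per-nutrient bias, noise and missingness, scores responses for
    external concordance against a food-composition reference table and
    internal concordance against prompt goals, aggregates reviewer
    annotations of qualitative usability errors by majority rule, and
    runs nonparametric comparisons of macronutrient versus micronutrient
    accuracy.
License: MIT + file LICENSE
Imports:
    dplyr,
    jsonlite,
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
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
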