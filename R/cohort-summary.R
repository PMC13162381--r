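#' Summarize a simulated cohort as a descriptive characteristics table
#'
#' Produces the one-row-per-characteristic table conventional for a study
#' population: mean (SD) for continuous characteristics, n (%) for
#' categorical ones. Threshold-type goals (the mineral and fluid maxima)
#' are formatted with a leading "< " to signal that they are daily caps,
#' not targets.
#'
#' @param cohort A tibble from [simulate_cohort()].
#' @return A tibble with columns `section`, `characteristic`, the numeric
#'   summaries `n`, `percent`, `mean`, `sd` (unused ones `NA`), and a
#'   preformatted `value` string.
#' @export
cohort_summary <- function(cohort) {
  if (is.null(nrow(cohort)) || nrow(cohort) == 0) {
    stop("cohort is empty", call. = FALSE)
  }
  n_total <- nrow(cohort)

  cont_row <- function(section, label, x, digits = 0, prefix = "") {
    m <- mean(x)
    s <- stats::sd(x)
    if (is.na(s)) s <- 0
    tibble::tibble(
      section = section, characteristic = label,
      n = NA_integer_, percent = NA_real_, mean = m, sd = s,
      value = sprintf("%s%s (%s)", prefix,
                      formatC(round(m, digits), format = "f",
                              digits = digits),
                      formatC(round(s, max(digits, if (s < 10) 1 else 0)),
                              format = "f",
                              digits = max(digits, if (s < 10) 1 else 0))))
  }
  cat_row <- function(section, label, count) {
    pct <- 100 * count / n_total
    tibble::tibble(
      section = section, characteristic = label,
      n = as.integer(count), percent = pct,
      mean = NA_real_, sd = NA_real_,
      value = sprintf("%d (%d%%)", as.integer(count), round(pct)))
  }

  dplyr::bind_rows(
    cont_row("Demographics", "Age in years", cohort$age),
    cat_row("Demographics", "Male", sum(cohort$sex == "male")),
    cat_row("Demographics", "Female", sum(cohort$sex == "female")),
    dplyr::bind_rows(lapply(names(sort(table(cohort$race),
                                       decreasing = TRUE)), function(r) {
      cat_row("Race", r, sum(cohort$race == r))
    })),
    cont_row("Biophysical factors", "BMI (kg/m2)", cohort$bmi, 1),
    cont_row("Biophysical factors", "Serum Albumin (g/dL)",
             cohort$albumin, 1),
    cont_row("Biophysical factors", "Serum Phosphorus (mg/dL)",
             cohort$serum_phosphorus, 1),
    cat_row("Comorbidities", "Hypertension", sum(cohort$hypertension)),
    cat_row("Comorbidities", "Diabetes", sum(cohort$diabetes)),
    cat_row("Comorbidities", "Congestive Heart Failure",
            sum(cohort$heart_failure)),
    cat_row("Financial and Socioeconomic Factors", "Fixed income",
            sum(cohort$fixed_income)),
    cat_row("Financial and Socioeconomic Factors", "Medicaid",
            sum(cohort$insurance == "Medicaid")),
    cat_row("Financial and Socioeconomic Factors", "Medicare",
            sum(cohort$insurance == "Medicare")),
    cat_row("Financial and Socioeconomic Factors", "Food Insecurity",
            sum(cohort$food_insecurity)),
    cont_row("Financial and Socioeconomic Factors",
             "Food Budget in dollars per day", cohort$budget, 2, "$"),
    cat_row("Food constraints", "Specific cuisine preference",
            sum(!is.na(cohort$cuisine_preference))),
    cat_row("Food constraints", "Vegetarian", sum(cohort$vegetarian)),
    cat_row("Food constraints", "Fish allergy", sum(cohort$fish_allergy)),
    cat_row("Food constraints", "Peanut allergy",
            sum(cohort$peanut_allergy)),
    cat_row("Food constraints", "Celiac disease", sum(cohort$celiac)),
    cont_row("Simulated Nutrition Goals", "Calories (kcal/day)",
             cohort$goal_calories),
    cont_row("Simulated Nutrition Goals", "Protein (g/day)",
             cohort$goal_protein),
    cont_row("Simulated Nutrition Goals", "Fiber (g/day)",
             cohort$goal_fiber),
    cont_row("Simulated Nutrition Goals", "Calcium (mg/day)",
             cohort$calcium_max, 0, "< "),
    cont_row("Simulated Nutrition Goals", "Phosphorus (mg/day)",
             cohort$phosphorus_max, 0, "< "),
    cont_row("Simulated Nutrition Goals", "Potassium (mg/day)",
             cohort$potassium_max, 0, "< "),
    cont_row("Simulated Nutrition Goals", "Sodium (mg/day)",
             cohort$sodium_max, 0, "< "),
    cont_row("Simulated Nutrition Goals", "Fluid (mL/day)",
             cohort$fluid_max, 0, "< "))
}
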