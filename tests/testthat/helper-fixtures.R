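# Fixtures built in code: a tiny food table with easy arithmetic, a
# hand-specified patient, and record constructors.

tiny_reference_table <- function() {
  tab <- tibble::tibble(
    source = c("USDA", "USDA", "USDA", "MW", "AUSNUT"),
    food_id = c("U1", "U2", "U3", "M1", "A1"),
    name = c("rice", "chicken", "apple", "milk", "bread"),
    calories_kcal = c(90, 200, 50, 60, 250),
    protein_g = c(2, 30, 0.5, 3, 9),
    fiber_g = c(1, 0, 2, 0, 3),
    calcium_mg = c(10, 20, 5, 120, 100),
    phosphorus_mg = c(50, 200, 10, 90, 100),
    potassium_mg = c(40, 250, 100, 150, 120),
    sodium_mg = c(5, 80, 1, 40, 400))
  suppressMessages(merge_reference_tables(tab))
}

tiny_mapping <- function() {
  tibble::tibble(
    item_name = c("rice", "chicken", "apple", "milk", "bread"),
    food_id = c("U1", "U2", "U3", "M1", "A1"),
    grams = c(150, 120, 100, 200, 60))
}

make_record <- function(response_id = "r1", prompt_id = "HD0001",
                        model_id = "model_A", item_names = "rice",
                        stated_totals = NULL) {
  items <- lapply(item_names, function(nm) {
    list(item_name = nm, portion_text = "1 portion", stated = list())
  })
  list(response_id = response_id, prompt_id = prompt_id,
       model_id = model_id,
       meals = list(list(meal_name = "Breakfast", items = items)),
       stated_daily_totals = stated_totals)
}

# The worked-example patient: every value as rendered in the prompt.
example_patient <- function() {
  tibble::tibble(
    id = "EX01", age = 62L, sex = "male", race = "Asian",
    height = 1.73, bmi = 29.1, dry_weight = 87,
    standardized_weight = 75, albumin = 2.9, serum_phosphorus = 6.4,
    hypertension = TRUE, diabetes = TRUE, heart_failure = TRUE,
    celiac = FALSE, vegetarian = FALSE,
    fish_allergy = FALSE, peanut_allergy = FALSE, pew = FALSE,
    cuisine_preference = NA_character_, food_insecurity = TRUE,
    fixed_income = TRUE, insurance = "Medicaid", budget = 12.5,
    goal_calories = 2150, goal_protein = 92, goal_fiber = 21,
    calcium_max = 950, phosphorus_max = 850, potassium_max = 2900,
    sodium_max = 1950, fluid_max = 1100)
}

example_prompt_text <- function() {
  paste0(
    "I am a 62-year-old Asian man on hemodialysis three times a week. ",
    "My dry weight is 87 kg and my BMI is 29.1. ",
    "My dietitian recommends I eat a diet with 92 g of protein, ",
    "2150 calories, and 21 g of fiber per day. ",
    "She also recommends no more than 850 mg of phosphorus, no more ",
    "than 950 mg of calcium, no more than 1950 mg of sodium, and no ",
    "more than 2900 mg per day of potassium. ",
    "She also recommends drinking no more than 1100 mL of fluids per ",
    "day. My albumin is 2.9 g/dL and my phosphorus is 6.4 mg/dL. ",
    "I do not have Celiac disease. I have no allergies. ",
    "I have no food preferences. My daily food budget is $12.5. ",
    "I am experiencing food insecurity. I am not a vegetarian. ",
    "I have heart failure. I have high blood pressure. I have diabetes. ",
    "Can you help me with meal planning? Look it up and please provide ",
    "a detailed meal plan that includes portion sizes. Please make sure ",
    "to include a list of how much protein, calories, fiber, sodium, ",
    "phosphorus, calcium, and potassium are in each meal, as well as ",
    "the daily totals. Please only include a meal plan for a single day.")
}

# Numerically integrated mean of a clipped log-normal: the independent
# oracle for the sampler's expectation. Integrates on the log scale,
# where the density mass is easy for the quadrature to find.
clipped_lognormal_mean <- function(mu_log, sigma, lo, hi) {
  f <- function(z) {
    pmin(pmax(exp(z), lo), hi) * stats::dnorm(z, mu_log, sigma)
  }
  stats::integrate(f, mu_log - 12 * sigma, mu_log + 12 * sigma,
                   rel.tol = 1e-10)$value
}

# Build an accuracy tibble whose per-response macro/micro internal
# concordance proportions are exactly as requested (for the paired test).
proportions_accuracy_table <- function(macro_props, micro_props) {
  flags_for <- function(p, k) c(rep(TRUE, round(p * k)),
                                rep(FALSE, k - round(p * k)))
  dplyr::bind_rows(lapply(seq_along(macro_props), function(i) {
    tibble::tibble(
      response_id = sprintf("r%02d", i),
      nutrient = c(macro_nutrients(), micro_nutrients()),
      internal_accurate = c(flags_for(macro_props[i], 3),
                            flags_for(micro_props[i], 4)),
      external_accurate = NA)
  }))
}
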