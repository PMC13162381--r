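#' Render the standardized meal-planning prompt for one patient
#'
#' Deterministically renders the conversational, zero-shot prompt that
#' presents a patient's demographics, goals, labs and constraints and asks
#' for a single-day meal plan with per-meal and daily nutrient lists.
#' Sentence order and phrasing are fixed; conditional sentences switch
#' between affirmative and negative forms (e.g. "I do not have Celiac
#' disease." / "I have Celiac disease."), comorbidity sentences are
#' included only when present, in the fixed order heart failure, high
#' blood pressure, diabetes, and the three closing instruction sentences
#' are always present verbatim.
#'
#' @param patient A one-row tibble combining profile and goal columns, as
#'   produced by [simulate_cohort()].
#' @return A single string, the prompt text. Every rounded goal value
#'   appears verbatim in the text.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n = 1, seed = 7))
#' cat(render_prompt(cohort[1, ]))
#' @export
render_prompt <- function(patient) {
  if (is.null(nrow(patient)) || nrow(patient) != 1) {
    stop("patient must be a single row", call. = FALSE)
  }
  required <- c("age", "sex", "race", "dry_weight", "bmi", "albumin",
                "serum_phosphorus", "celiac", "fish_allergy",
                "peanut_allergy", "budget", "food_insecurity", "vegetarian",
                "heart_failure", "hypertension", "diabetes",
                "goal_calories", "goal_protein", "goal_fiber",
                "calcium_max", "phosphorus_max", "potassium_max",
                "sodium_max", "fluid_max")
  for (field in required) {
    if (is.null(patient[[field]]) || is.na(patient[[field]])) {
      stop("missing required field: ", field, call. = FALSE)
    }
  }
  p <- as.list(patient)

  sex_word <- if (p$sex == "male") "man" else "woman"
  sentences <- c(
    sprintf("I am a %d-year-old %s %s on hemodialysis three times a week.",
            p$age, p$race, sex_word),
    sprintf("My dry weight is %s kg and my BMI is %s.",
            fmt_num(p$dry_weight, 1), fmt_num(p$bmi, 1)),
    sprintf(paste("My dietitian recommends I eat a diet with %s g of",
                  "protein, %s calories, and %s g of fiber per day."),
            fmt_num(p$goal_protein), fmt_num(p$goal_calories),
            fmt_num(p$goal_fiber)),
    sprintf(paste("She also recommends no more than %s mg of phosphorus,",
                  "no more than %s mg of calcium, no more than %s mg of",
                  "sodium, and no more than %s mg per day of potassium."),
            fmt_num(p$phosphorus_max), fmt_num(p$calcium_max),
            fmt_num(p$sodium_max), fmt_num(p$potassium_max)),
    sprintf("She also recommends drinking no more than %s mL of fluids per day.",
            fmt_num(p$fluid_max)),
    sprintf("My albumin is %s g/dL and my phosphorus is %s mg/dL.",
            fmt_num(p$albumin, 1), fmt_num(p$serum_phosphorus, 1)),
    if (p$celiac) "I have Celiac disease." else
      "I do not have Celiac disease.",
    allergy_sentence(p$fish_allergy, p$peanut_allergy),
    if (!is.null(p$cuisine_preference) && !is.na(p$cuisine_preference)) {
      sprintf("I prefer %s food.", p$cuisine_preference)
    } else {
      "I have no food preferences."
    },
    sprintf("My daily food budget is $%s.", fmt_num(p$budget, 2)),
    if (p$food_insecurity) "I am experiencing food insecurity." else
      "I am not experiencing food insecurity.",
    if (p$vegetarian) "I am a vegetarian." else "I am not a vegetarian.",
    if (p$heart_failure) "I have heart failure.",
    if (p$hypertension) "I have high blood pressure.",
    if (p$diabetes) "I have diabetes.",
    paste("Can you help me with meal planning? Look it up and please",
          "provide a detailed meal plan that includes portion sizes.",
          "Please make sure to include a list of how much protein,",
          "calories, fiber, sodium, phosphorus, calcium, and potassium",
          "are in each meal, as well as the daily totals. Please only",
          "include a meal plan for a single day."))
  paste(sentences[!vapply(sentences, is.null, logical(1))], collapse = " ")
}

allergy_sentence <- function(fish, peanut) {
  items <- c(if (fish) "fish", if (peanut) "peanut")
  if (length(items) == 0) return("I have no allergies.")
  sprintf("I am allergic to %s.", paste(items, collapse = " and "))
}

#' Render prompts for a whole cohort
#'
#' @param cohort A tibble from [simulate_cohort()].
#' @return A tibble with one row per patient: `prompt_id` (equal to the
#'   patient id; one prompt per patient), `patient_id`, and the prompt
#'   `text`.
#' @export
render_prompts <- function(cohort) {
  if (is.null(nrow(cohort)) || nrow(cohort) == 0) {
    stop("cohort is empty", call. = FALSE)
  }
  tibble::tibble(
    prompt_id = cohort$id,
    patient_id = cohort$id,
    text = vapply(seq_len(nrow(cohort)),
                  function(i) render_prompt(cohort[i, ]), character(1)))
}
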