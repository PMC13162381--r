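#' Configuration for the hypothetical hemodialysis cohort simulator
#'
#' Bundles every distribution parameter used to simulate patient profiles
#' and their individualized nutrition goals. The defaults encode the study
#' conditions of the evaluation framework: prevalences mirroring the US
#' hemodialysis population, guideline-derived goal rules (35 kcal/kg/day
#' under age 60, 30--35 kcal/kg/day at 60 and over; 1.2 g protein/kg/day,
#' 1.3 with protein-energy wasting), and log-normal mineral maxima clipped
#' to guideline bounds.
#'
#' @param n Cohort size.
#' @param seed Optional integer seed applied by [simulate_cohort()].
#' @param sex_prevalence,race_prevalence,insurance_prevalence Named
#'   probability vectors (must sum to 1).
#' @param hypertension,diabetes,heart_failure,celiac,vegetarian,fish_allergy,peanut_allergy
#'   Bernoulli prevalences of comorbidities and dietary constraints.
#' @param food_insecurity Prevalence of food insecurity (default 0.2615).
#' @param pew Prevalence of protein-energy wasting (default 0.33).
#' @param fixed_income Prevalence of fixed-income status (default 0.82).
#' @param cuisine_none Probability of no cuisine preference (default 0.5).
#' @param cuisines Character vector of cuisine names to draw from, with
#'   equal probability, when a preference is present.
#' @param age_mean,age_sd,age_range Age distribution (years); draws are
#'   rounded to whole years and clipped to `age_range`.
#' @param bmi_mean,bmi_sd,bmi_range Body-mass index (kg/m^2), clipped.
#' @param height_mean Named vector `c(male = , female = )` of mean heights
#'   in metres; `height_sd` the common SD.
#' @param height_sd Height standard deviation (m).
#' @param albumin_mean,albumin_sd,albumin_range Serum albumin (g/dL).
#' @param phosphorus_mean,phosphorus_sd,phosphorus_range Serum phosphorus
#'   (mg/dL).
#' @param budget_mean Named vector `c(fixed = , nonfixed = )` of mean daily
#'   food budgets (USD/day); `budget_sd` the common within-group SD.
#' @param budget_sd Budget standard deviation (USD/day).
#' @param weight_basis Dosing ("standardized") weight used to scale per-kg
#'   goals: `"adjusted"` (ideal body weight by the Devine formula plus
#'   `weight_adjustment` times the dry-weight excess) or `"dry"` (dry
#'   weight itself).
#' @param weight_adjustment Fraction of the excess over ideal body weight
#'   included in the adjusted weight (default 0.25).
#' @param calorie_rate_senior `c(mean, sd)` of the kcal/kg/day rate drawn
#'   for patients aged 60+; clipped to `calorie_rate_bounds`.
#' @param calorie_rate_bounds Clipping bounds for the senior calorie rate.
#' @param calorie_rate_junior Fixed kcal/kg/day rate under age 60.
#' @param protein_rate Named vector `c(standard = 1.2, pew = 1.3)` in
#'   g/kg/day.
#' @param fiber `c(mean, sd)` of the fiber target (g/day).
#' @param sodium,calcium,potassium Lists `list(mu_log, sigma, lo, hi)`
#'   parameterizing the clipped log-normal daily maxima (mg/day).
#' @param phosphorus_rate_high,phosphorus_rate_normal `c(mean, sd)` of the
#'   phosphorus maximum rate (mg/kg/day) used when serum phosphorus is
#'   above (strictly) versus at-or-below `phosphorus_cutoff` mg/dL.
#' @param phosphorus_cutoff Serum phosphorus cutoff (mg/dL, default 5.5).
#' @param fluid List `list(mean, sd, lo, hi)` for the fluid maximum
#'   (mL/day), a clipped normal.
#' @param round_unit Rounding granularity applied to calories, the four
#'   mineral maxima and fluid (default 50); protein and fiber are rounded
#'   to whole grams and budgets to USD 0.50, matching prompt granularity.
#' @return A list of class `cohort_config`.
#' @seealso [simulate_cohort()], [derive_goals()]
#' @export
cohort_config <- function(
    n = 50,
    seed = NULL,
    sex_prevalence = c(male = 0.58, female = 0.42),
    race_prevalence = c(Asian = 0.10, Black = 0.42, Hispanic = 0.16,
                        `Native Hawaiian/Pacific Islander` = 0.02,
                        White = 0.30),
    insurance_prevalence = c(Medicaid = 0.22, Medicare = 0.52, other = 0.26),
    hypertension = 0.88, diabetes = 0.58, heart_failure = 0.28,
    celiac = 0.01, vegetarian = 0.02,
    fish_allergy = 0.02, peanut_allergy = 0.02,
    food_insecurity = 0.2615, pew = 0.33, fixed_income = 0.82,
    cuisine_none = 0.50,
    cuisines = c("Spanish", "British", "French", "German", "Italian",
                 "Greek", "Saudi Arabian", "Emirati", "Indian", "Chinese",
                 "Thai", "Malaysian", "Vietnamese", "Korean", "Filipino",
                 "Indonesian", "Australian", "Japanese", "American",
                 "Mexican", "Caribbean"),
    age_mean = 63, age_sd = 14, age_range = c(18, 95),
    bmi_mean = 29.7, bmi_sd = 1.8, bmi_range = c(15, 45),
    height_mean = c(male = 1.76, female = 1.62), height_sd = 0.07,
    albumin_mean = 3.1, albumin_sd = 0.3, albumin_range = c(1.5, 5.0),
    phosphorus_mean = 5.0, phosphorus_sd = 1.1, phosphorus_range = c(2, 9),
    budget_mean = c(fixed = 12, nonfixed = 15), budget_sd = 1.2,
    weight_basis = c("adjusted", "dry"), weight_adjustment = 0.25,
    calorie_rate_senior = c(mean = 32.5, sd = 1.25),
    calorie_rate_bounds = c(30, 35),
    calorie_rate_junior = 35,
    protein_rate = c(standard = 1.2, pew = 1.3),
    fiber = c(mean = 22.5, sd = 1.25),
    sodium = list(mu_log = log(2000), sigma = 0.1, lo = 750, hi = 2000),
    calcium = list(mu_log = log(1000), sigma = 0.1, lo = 600, hi = 1000),
    potassium = list(mu_log = log(2730), sigma = 0.1, lo = 1800, hi = 3120),
    phosphorus_rate_high = c(mean = 12, sd = 1),
    phosphorus_rate_normal = c(mean = 14, sd = 1),
    phosphorus_cutoff = 5.5,
    fluid = list(mean = 1172, sd = 99, lo = 800, hi = 1500),
    round_unit = 50) {
  weight_basis <- match.arg(weight_basis)
  cfg <- list(
    n = n, seed = seed,
    sex_prevalence = sex_prevalence, race_prevalence = race_prevalence,
    insurance_prevalence = insurance_prevalence,
    hypertension = hypertension, diabetes = diabetes,
    heart_failure = heart_failure, celiac = celiac, vegetarian = vegetarian,
    fish_allergy = fish_allergy, peanut_allergy = peanut_allergy,
    food_insecurity = food_insecurity, pew = pew, fixed_income = fixed_income,
    cuisine_none = cuisine_none, cuisines = cuisines,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd, bmi_range = bmi_range,
    height_mean = height_mean, height_sd = height_sd,
    albumin_mean = albumin_mean, albumin_sd = albumin_sd,
    albumin_range = albumin_range,
    phosphorus_mean = phosphorus_mean, phosphorus_sd = phosphorus_sd,
    phosphorus_range = phosphorus_range,
    budget_mean = budget_mean, budget_sd = budget_sd,
    weight_basis = weight_basis, weight_adjustment = weight_adjustment,
    calorie_rate_senior = calorie_rate_senior,
    calorie_rate_bounds = calorie_rate_bounds,
    calorie_rate_junior = calorie_rate_junior,
    protein_rate = protein_rate, fiber = fiber,
    sodium = sodium, calcium = calcium, potassium = potassium,
    phosphorus_rate_high = phosphorus_rate_high,
    phosphorus_rate_normal = phosphorus_rate_normal,
    phosphorus_cutoff = phosphorus_cutoff,
    fluid = fluid, round_unit = round_unit)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  for (nm in c("hypertension", "diabetes", "heart_failure", "celiac",
               "vegetarian", "fish_allergy", "peanut_allergy",
               "food_insecurity", "pew", "fixed_income", "cuisine_none")) {
    check_prob(cfg[[nm]], nm)
  }
  for (nm in c("sex_prevalence", "race_prevalence", "insurance_prevalence")) {
    check_prob(cfg[[nm]], nm)
    if (abs(sum(cfg[[nm]]) - 1) > 1e-8) {
      stop(nm, " must sum to 1", call. = FALSE)
    }
  }
  sds <- c(cfg$age_sd, cfg$bmi_sd, cfg$height_sd, cfg$albumin_sd,
           cfg$phosphorus_sd, cfg$budget_sd, cfg$calorie_rate_senior[["sd"]],
           cfg$fiber[["sd"]], cfg$phosphorus_rate_high[["sd"]],
           cfg$phosphorus_rate_normal[["sd"]], cfg$fluid$sd,
           cfg$sodium$sigma, cfg$calcium$sigma, cfg$potassium$sigma)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("all standard deviations must be non-negative", call. = FALSE)
  }
  for (nm in c("sodium", "calcium", "potassium")) {
    if (cfg[[nm]]$lo > cfg[[nm]]$hi) {
      stop("invalid ", nm, " bounds: lo > hi", call. = FALSE)
    }
  }
  if (cfg$cuisine_none < 1 && length(cfg$cuisines) == 0) {
    stop("cuisines must be non-empty when cuisine_none < 1", call. = FALSE)
  }
  invisible(cfg)
}

## Devine ideal body weight (kg) from sex and height; the height excess
## over 5 ft is floored at zero.
devine_ibw <- function(sex, height_m) {
  inches_over <- pmax(height_m / 0.0254 - 60, 0)
  ifelse(sex == "male", 50, 45.5) + 2.3 * inches_over
}

standardized_weight <- function(sex, height, dry_weight, config) {
  if (config$weight_basis == "dry") return(dry_weight)
  ibw <- devine_ibw(sex, height)
  round(ibw + config$weight_adjustment * (dry_weight - ibw), 1)
}

#' Sample hypothetical hemodialysis patient profiles
#'
#' Draws `n` patient profiles (demographics, anthropometrics, labs,
#' comorbidities and socioeconomic factors) from the distributions in a
#' [cohort_config()]. Uses the current RNG state; seed handling lives in
#' [simulate_cohort()].
#'
#' @param config A [cohort_config()].
#' @param n Number of profiles (defaults to `config$n`).
#' @return A tibble with one row per patient: identifiers, `age`, `sex`,
#'   `race`, `height` (m), `bmi`, `dry_weight` (kg, `bmi * height^2`),
#'   `standardized_weight` (the dosing weight), `albumin`,
#'   `serum_phosphorus`, comorbidity and constraint booleans,
#'   `cuisine_preference` (`NA` when none), `insurance` and `budget`
#'   (USD/day).
#' @export
sample_profiles <- function(config, n = config$n) {
  if (!inherits(config, "cohort_config")) {
    stop("config must be a cohort_config", call. = FALSE)
  }
  if (n < 1) stop("n must be at least 1", call. = FALSE)

  sex <- sample(names(config$sex_prevalence), n, TRUE, config$sex_prevalence)
  race <- sample(names(config$race_prevalence), n, TRUE,
                 config$race_prevalence)
  age <- as.integer(round(clip(rnorm(n, config$age_mean, config$age_sd),
                               config$age_range[1], config$age_range[2])))
  height <- round(rnorm(n, config$height_mean[sex], config$height_sd), 2)
  bmi <- round(clip(rnorm(n, config$bmi_mean, config$bmi_sd),
                    config$bmi_range[1], config$bmi_range[2]), 1)
  dry_weight <- round(bmi * height^2)
  albumin <- round(clip(rnorm(n, config$albumin_mean, config$albumin_sd),
                        config$albumin_range[1], config$albumin_range[2]), 1)
  serum_phosphorus <- round(
    clip(rnorm(n, config$phosphorus_mean, config$phosphorus_sd),
         config$phosphorus_range[1], config$phosphorus_range[2]), 1)

  draw <- function(p) rbinom(n, 1, p) == 1
  hypertension <- draw(config$hypertension)
  diabetes <- draw(config$diabetes)
  heart_failure <- draw(config$heart_failure)
  celiac <- draw(config$celiac)
  vegetarian <- draw(config$vegetarian)
  fish_allergy <- draw(config$fish_allergy)
  peanut_allergy <- draw(config$peanut_allergy)
  food_insecurity <- draw(config$food_insecurity)
  pew <- draw(config$pew)
  fixed_income <- draw(config$fixed_income)

  has_pref <- runif(n) >= config$cuisine_none
  cuisine_preference <- rep(NA_character_, n)
  if (any(has_pref)) {
    cuisine_preference[has_pref] <- sample(config$cuisines, sum(has_pref),
                                           replace = TRUE)
  }
  insurance <- sample(names(config$insurance_prevalence), n, TRUE,
                      config$insurance_prevalence)
  budget_centre <- ifelse(fixed_income, config$budget_mean[["fixed"]],
                          config$budget_mean[["nonfixed"]])
  budget <- clip(round_to(rnorm(n, budget_centre, config$budget_sd), 0.5),
                 5, 30)

  tibble::tibble(
    id = sprintf("HD%04d", seq_len(n)),
    age = age, sex = sex, race = race,
    height = height, bmi = bmi, dry_weight = dry_weight,
    standardized_weight = standardized_weight(sex, height, dry_weight,
                                              config),
    albumin = albumin, serum_phosphorus = serum_phosphorus,
    hypertension = hypertension, diabetes = diabetes,
    heart_failure = heart_failure, celiac = celiac,
    vegetarian = vegetarian, fish_allergy = fish_allergy,
    peanut_allergy = peanut_allergy, pew = pew,
    cuisine_preference = cuisine_preference,
    food_insecurity = food_insecurity, fixed_income = fixed_income,
    insurance = insurance, budget = budget)
}

#' Derive individualized daily nutrition goals for patient profiles
#'
#' Applies the guideline-based goal rules to each profile: calories at
#' 35 kcal/kg/day under age 60 and at a rate drawn from
#' `N(32.5, 1.25^2)` clipped to 30--35 at age 60+; protein at 1.2 g/kg/day
#' (1.3 with protein-energy wasting); a fiber target from `N(22.5, 1.25^2)`
#' g/day; a phosphorus maximum at a rate drawn from `N(12, 1)` mg/kg/day
#' when serum phosphorus exceeds 5.5 mg/dL and `N(14, 1)` otherwise; and
#' sodium, calcium and potassium maxima from clipped log-normals (see
#' [sample_truncated_lognormal()]). All per-kg rates scale the
#' standardized (dosing) weight. Goals are rounded to prompt granularity:
#' calories, mineral maxima and fluid to the nearest `round_unit`
#' (default 50), protein and fiber to whole grams.
#'
#' @param profiles A tibble from [sample_profiles()] (or compatible rows).
#' @param config A [cohort_config()].
#' @return A tibble with columns `goal_calories` (kcal/day), `goal_protein`
#'   and `goal_fiber` (g/day), and daily maxima `calcium_max`,
#'   `phosphorus_max`, `potassium_max`, `sodium_max` (mg/day) and
#'   `fluid_max` (mL/day).
#' @export
derive_goals <- function(profiles, config = cohort_config()) {
  n <- nrow(profiles)
  if (is.null(n) || n < 1) stop("profiles must have at least one row",
                                call. = FALSE)
  if (any(is.na(profiles$serum_phosphorus))) {
    stop("serum_phosphorus is missing: phosphorus goal branch undecidable",
         call. = FALSE)
  }
  w <- profiles$standardized_weight

  senior_rate <- clip(rnorm(n, config$calorie_rate_senior[["mean"]],
                            config$calorie_rate_senior[["sd"]]),
                      config$calorie_rate_bounds[1],
                      config$calorie_rate_bounds[2])
  cal_rate <- ifelse(profiles$age < 60, config$calorie_rate_junior,
                     senior_rate)
  protein_rate <- ifelse(profiles$pew, config$protein_rate[["pew"]],
                         config$protein_rate[["standard"]])
  fiber <- rnorm(n, config$fiber[["mean"]], config$fiber[["sd"]])

  ## both branch rates are drawn for every patient so the vector of random
  ## draws has fixed length regardless of the serum phosphorus values
  rate_high <- rnorm(n, config$phosphorus_rate_high[["mean"]],
                     config$phosphorus_rate_high[["sd"]])
  rate_normal <- rnorm(n, config$phosphorus_rate_normal[["mean"]],
                       config$phosphorus_rate_normal[["sd"]])
  phos_rate <- ifelse(profiles$serum_phosphorus > config$phosphorus_cutoff,
                      rate_high, rate_normal)

  sodium <- sample_truncated_lognormal(n, config$sodium$mu_log,
                                       config$sodium$sigma,
                                       config$sodium$lo, config$sodium$hi)
  calcium <- sample_truncated_lognormal(n, config$calcium$mu_log,
                                        config$calcium$sigma,
                                        config$calcium$lo, config$calcium$hi)
  potassium <- sample_truncated_lognormal(n, config$potassium$mu_log,
                                          config$potassium$sigma,
                                          config$potassium$lo,
                                          config$potassium$hi)
  fluid <- clip(rnorm(n, config$fluid$mean, config$fluid$sd),
                config$fluid$lo, config$fluid$hi)

  u <- config$round_unit
  tibble::tibble(
    goal_calories = round_to(cal_rate * w, u),
    goal_protein = round(protein_rate * w),
    goal_fiber = round(fiber),
    calcium_max = round_to(calcium, u),
    phosphorus_max = round_to(phos_rate * w, u),
    potassium_max = round_to(potassium, u),
    sodium_max = round_to(sodium, u),
    fluid_max = round_to(fluid, u))
}

#' Simulate a cohort of hypothetical hemodialysis patients with goals
#'
#' Draws `config$n` patient profiles and their individualized nutrition
#' goals. Reproducible: when `config$seed` is set the same cohort is
#' produced on every call.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per patient, combining the columns of
#'   [sample_profiles()] and [derive_goals()].
#' @examples
#' cohort <- simulate_cohort(cohort_config(n = 5, seed = 42))
#' cohort$sodium_max   # all within [750, 2000]
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    stop("config must be a cohort_config", call. = FALSE)
  }
  if (config$n < 1) stop("cohort size n must be at least 1", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  profiles <- sample_profiles(config)
  goals <- derive_goals(profiles, config)
  dplyr::bind_cols(profiles, goals)
}
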