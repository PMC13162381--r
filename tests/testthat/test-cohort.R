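test_that("cohort simulation is reproducible under a fixed seed", {
  a <- simulate_cohort(cohort_config(n = 8, seed = 17))
  b <- simulate_cohort(cohort_config(n = 8, seed = 17))
  expect_identical(a, b)
  d <- simulate_cohort(cohort_config(n = 8, seed = 18))
  expect_false(isTRUE(all.equal(a, d)))
})

test_that("cohort size and config validation are enforced", {
  expect_error(simulate_cohort(cohort_config(n = 0, seed = 1)),
               "at least 1")
  expect_error(cohort_config(food_insecurity = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(sex_prevalence = c(male = 0.7, female = 0.7)),
               "sum to 1")
  expect_error(cohort_config(cuisine_none = 0.5, cuisines = character(0)),
               "non-empty")
  expect_error(cohort_config(sodium = list(mu_log = log(2000), sigma = 0.1,
                                           lo = 3000, hi = 2000)),
               "lo > hi")
})

test_that("degenerate prevalences propagate to every profile", {
  cohort <- simulate_cohort(cohort_config(n = 30, seed = 2,
                                          food_insecurity = 1,
                                          vegetarian = 0))
  expect_true(all(cohort$food_insecurity))
  expect_false(any(cohort$vegetarian))
})

test_that("configured prevalences are recovered at large n", {
  cohort <- simulate_cohort(cohort_config(n = 1e4, seed = 5))
  checks <- c(food_insecurity = 0.2615, pew = 0.33, hypertension = 0.88,
              diabetes = 0.58, fixed_income = 0.82)
  for (nm in names(checks)) {
    p <- checks[[nm]]
    se <- sqrt(p * (1 - p) / 1e4)
    expect_lt(abs(mean(cohort[[nm]]) - p), 3 * se)
  }
  # cuisine preference present for about half the cohort
  p_pref <- mean(!is.na(cohort$cuisine_preference))
  expect_lt(abs(p_pref - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("profile anthropometrics are internally consistent", {
  cohort <- simulate_cohort(cohort_config(n = 500, seed = 6))
  expect_true(all(cohort$age >= 18 & cohort$age <= 95))
  expect_true(all(abs(cohort$dry_weight - cohort$bmi * cohort$height^2)
                  <= 0.5))
  expect_true(all(cohort$budget > 0))
})

test_that("deterministic goal branches follow the per-kg rules", {
  profile <- tibble::tibble(age = 59L, standardized_weight = 80,
                            pew = FALSE, serum_phosphorus = 5.0)
  goals <- derive_goals(profile, cohort_config())
  expect_equal(goals$goal_calories, 2800)  # 35 kcal/kg x 80 kg
  expect_equal(goals$goal_protein, 96)     # 1.2 g/kg x 80 kg

  pew_profile <- dplyr::mutate(profile, pew = TRUE)
  expect_equal(derive_goals(pew_profile, cohort_config())$goal_protein,
               104)                        # 1.3 g/kg x 80 kg
})

test_that("phosphorus rate branches strictly at the serum cutoff", {
  cfg <- cohort_config(round_unit = 1)
  base <- tibble::tibble(age = 50L, standardized_weight = 80, pew = FALSE,
                         serum_phosphorus = 7.0)
  n <- 2000
  high <- base[rep(1, n), ]
  withr::with_seed(31, g_high <- derive_goals(high, cfg))
  rate_high <- g_high$phosphorus_max / 80
  expect_lt(abs(mean(rate_high) - 12), 3 / sqrt(n) + 0.05)

  low <- dplyr::mutate(high, serum_phosphorus = 4.0)
  withr::with_seed(32, g_low <- derive_goals(low, cfg))
  expect_lt(abs(mean(g_low$phosphorus_max / 80) - 14), 3 / sqrt(n) + 0.05)

  # exactly at the cutoff the higher-allowance branch applies
  at <- dplyr::mutate(high, serum_phosphorus = 5.5)
  withr::with_seed(33, g_at <- derive_goals(at, cfg))
  expect_lt(abs(mean(g_at$phosphorus_max / 80) - 14), 3 / sqrt(n) + 0.05)

  expect_error(derive_goals(dplyr::mutate(base,
                                          serum_phosphorus = NA_real_),
                            cfg),
               "undecidable")
})

test_that("with all spreads zero the goals equal their closed forms", {
  cfg <- cohort_config(
    n = 5, seed = 44, age_mean = 70, age_sd = 0,
    bmi_sd = 0, height_sd = 0, albumin_sd = 0, phosphorus_sd = 0,
    budget_sd = 0,
    calorie_rate_senior = c(mean = 32.5, sd = 0),
    fiber = c(mean = 22.5, sd = 0),
    sodium = list(mu_log = log(2000), sigma = 0, lo = 750, hi = 2000),
    calcium = list(mu_log = log(1000), sigma = 0, lo = 600, hi = 1000),
    potassium = list(mu_log = log(2730), sigma = 0, lo = 1800, hi = 3120),
    phosphorus_rate_high = c(mean = 12, sd = 0),
    phosphorus_rate_normal = c(mean = 14, sd = 0),
    fluid = list(mean = 1172, sd = 0, lo = 800, hi = 1500))
  cohort <- simulate_cohort(cfg)
  expect_equal(unique(cohort$sodium_max), 2000)
  expect_equal(unique(cohort$calcium_max), 1000)
  expect_equal(unique(cohort$potassium_max), round(2730 / 50) * 50)
  expect_equal(unique(cohort$fluid_max), round(1172 / 50) * 50)
  expect_equal(unique(cohort$goal_fiber), 22)  # round(22.5) rounds to even
  expect_equal(cohort$goal_calories,
               round(32.5 * cohort$standardized_weight / 50) * 50)
})

test_that("mineral maxima never leave their truncation bounds", {
  cohort <- simulate_cohort(cohort_config(n = 2e4, seed = 8))
  expect_true(all(cohort$sodium_max >= 750 & cohort$sodium_max <= 2000))
  expect_true(all(cohort$calcium_max >= 600 & cohort$calcium_max <= 1000))
  expect_true(all(cohort$potassium_max >= 1800 &
                    cohort$potassium_max <= 3120))
})

test_that("cohort summary reports mean (SD) and n (%) correctly", {
  cohort <- simulate_cohort(cohort_config(n = 50, seed = 12))
  tab <- cohort_summary(cohort)

  fiber_row <- tab[tab$characteristic == "Fiber (g/day)", ]
  expect_lt(abs(fiber_row$mean - 22.5), 3 * 1.25 / sqrt(50) + 0.5)

  sodium_row <- tab[tab$characteristic == "Sodium (mg/day)", ]
  expect_match(sodium_row$value, "^< \\d+ \\(\\d+(\\.\\d)?\\)$")
  expect_equal(sodium_row$mean, mean(cohort$sodium_max))

  male_row <- tab[tab$characteristic == "Male", ]
  expect_equal(male_row$n, sum(cohort$sex == "male"))
  expect_equal(male_row$percent, 100 * mean(cohort$sex == "male"))

  # identical patients: all continuous spreads are zero
  clones <- cohort[rep(1, 4), ]
  tab1 <- cohort_summary(clones)
  expect_true(all(tab1$sd[!is.na(tab1$sd)] == 0))

  expect_error(cohort_summary(cohort[0, ]), "empty")
})
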