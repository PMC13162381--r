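small_cohort <- function(n = 4, seed = 51) {
  simulate_cohort(cohort_config(n = n, seed = seed))
}

test_that("responses survive a JSON-lines round trip", {
  cohort <- small_cohort()
  synth <- synthesize_responses(cohort, tiny_reference_table(),
                                realistic_error_model(),
                                models = c("m1", "m2"), seed = 7)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_responses(synth$records, path)
  back <- read_responses(path)
  expect_equal(length(back), length(synth$records))
  expect_equal(back[[3]]$response_id, synth$records[[3]]$response_id)
  expect_equal(unlist(back[[3]]$stated_daily_totals),
               unlist(synth$records[[3]]$stated_daily_totals))
  expect_equal(back[[1]]$meals[[1]]$items[[1]]$item_name,
               synth$records[[1]]$meals[[1]]$items[[1]]$item_name)
})

test_that("schema violations are rejected with the record index", {
  good <- make_record(stated_totals = list(calories = 100))
  bad_neg <- make_record(response_id = "r2",
                         stated_totals = list(protein = -5))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_responses(list(good, bad_neg), path)
  expect_error(read_responses(path), "negative stated value.*record 2")

  no_meals <- list(response_id = "r3", prompt_id = "p", model_id = "m",
                   meals = list())
  path2 <- withr::local_tempfile(fileext = ".jsonl")
  write_responses(list(no_meals), path2)
  expect_error(read_responses(path2), "no meals")
})

test_that("a record omitting a micronutrient is accepted as missing", {
  rec <- make_record(stated_totals = list(calories = 500, protein = 20))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_responses(list(rec), path)
  back <- read_responses(path)
  stated <- renalmeal:::stated_totals_all(back)
  expect_true(is.na(stated$stated[stated$nutrient == "calcium"]))
  expect_equal(stated$stated[stated$nutrient == "calories"], 500)
})

test_that("the identity error model states exactly the reference totals", {
  cohort <- small_cohort()
  tab <- tiny_reference_table()
  synth <- synthesize_responses(cohort, tab, response_error_model(),
                                models = "m1", seed = 13)
  stated <- renalmeal:::stated_totals_all(synth$records)
  refs <- reference_totals_all(synth$records, synth$mapping, tab)
  joined <- dplyr::inner_join(stated, refs,
                              by = c("response_id", "nutrient"))
  expect_equal(joined$stated, joined$reference)
  expect_true(all(external_flag(joined$stated, joined$reference)))
})

test_that("a pure multiplicative bias is reproduced exactly", {
  cohort <- small_cohort()
  tab <- tiny_reference_table()
  em <- response_error_model(bias = c(potassium = 0.8))
  synth <- synthesize_responses(cohort, tab, em, models = "m1", seed = 13)
  stated <- renalmeal:::stated_totals_all(synth$records)
  refs <- reference_totals_all(synth$records, synth$mapping, tab)
  joined <- dplyr::inner_join(stated, refs,
                              by = c("response_id", "nutrient"))
  k <- joined[joined$nutrient == "potassium", ]
  expect_equal(k$stated / k$reference, rep(0.8, nrow(k)))
  other <- joined[joined$nutrient != "potassium", ]
  expect_equal(other$stated, other$reference)
})

test_that("certain missingness removes the nutrient everywhere", {
  cohort <- small_cohort()
  em <- response_error_model(missing_prob = c(calcium = 1))
  synth <- synthesize_responses(cohort, tiny_reference_table(), em,
                                models = "m1", seed = 13)
  for (rec in synth$records) {
    expect_false("calcium" %in% names(rec$stated_daily_totals))
    for (meal in rec$meals) {
      for (item in meal$items) {
        expect_false("calcium" %in% names(item$stated))
      }
    }
  }
})

test_that("goal-driven responses state the prompt goals", {
  cohort <- small_cohort()
  em <- response_error_model(mode = "goal_driven")
  synth <- synthesize_responses(cohort, tiny_reference_table(), em,
                                models = "m1", seed = 13)
  stated <- renalmeal:::stated_totals_all(synth$records)
  goals <- tidyr::pivot_longer(
    cohort[, c("id", "goal_calories", "goal_protein", "goal_fiber",
               "calcium_max", "phosphorus_max", "potassium_max",
               "sodium_max")],
    -id, names_to = "col", values_to = "goal")
  goals$nutrient <- sub("goal_", "", sub("_max", "", goals$col))
  joined <- dplyr::inner_join(stated, goals,
                              by = c(prompt_id = "id", "nutrient"))
  expect_equal(joined$stated, joined$goal)
})

test_that("sloppy sums decouple daily totals from item sums", {
  cohort <- small_cohort()
  em <- response_error_model(sloppy_sum_sigma = 0.2)
  synth <- synthesize_responses(cohort, tiny_reference_table(), em,
                                models = "m1", seed = 13)
  stated <- renalmeal:::stated_totals_all(synth$records, "stated_totals")
  summed <- renalmeal:::stated_totals_all(synth$records, "sum_items")
  expect_false(isTRUE(all.equal(stated$stated, summed$stated)))
})

test_that("error-model parameters are validated", {
  expect_error(response_error_model(bias = 0), "positive")
  expect_error(response_error_model(noise_sigma = -1), "non-negative")
  expect_error(response_error_model(missing_prob = 2), "\\[0, 1\\]")
  expect_error(response_error_model(bias = c(zinc = 1)), "unknown nutrient")
  expect_error(synthesize_responses(small_cohort(),
                                    tiny_reference_table()[0, ],
                                    response_error_model()),
               "empty")
})
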