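test_that("external flags implement the inclusive tolerance band", {
  expect_false(external_flag(25, 90))           # far outside +/-10%
  expect_true(external_flag(90, 90))
  expect_true(external_flag(99, 90))            # ratio exactly 1.10
  expect_true(external_flag(81, 90))            # ratio exactly 0.90
  expect_false(external_flag(99.1, 90))
  expect_false(external_flag(80.9, 90))
  # zero reference: concordant only with zero stated
  expect_true(external_flag(0, 0))
  expect_false(external_flag(0.1, 0))
  expect_true(is.na(external_flag(NA, 90)))
  expect_error(external_flag(-1, 90), "non-negative")
})

test_that("internal flags distinguish targets from thresholds", {
  expect_true(internal_flag(1800, 2000, "target"))
  expect_false(internal_flag(1799, 2000, "target"))
  expect_true(internal_flag(2200, 2000, "target"))
  expect_false(internal_flag(2201, 2000, "target"))
  expect_true(internal_flag(600, 2000, "threshold"))   # far under a cap
  expect_true(internal_flag(2200, 2000, "threshold"))  # exactly 110%
  expect_false(internal_flag(2201, 2000, "threshold"))
  expect_error(internal_flag(1, 2000, "maximum"), "unknown goal_type")
  expect_error(internal_flag(1, 0, "target"), "positive")
})

test_that("the target rule and the external rule are the same predicate", {
  withr::with_seed(61, {
    stated <- runif(500, 0, 300)
    ref <- runif(500, 1, 300)
  })
  expect_identical(external_flag(stated, ref),
                   internal_flag(stated, ref, "target"))
})

test_that("scored fixture matches a hand recount", {
  # 2 responses x 7 nutrients against goal 100 (targets) / cap 100
  # (thresholds) and reference 100; stated chosen around the boundaries.
  tab <- tiny_reference_table()
  cohort <- simulate_cohort(cohort_config(n = 1, seed = 62))
  cohort$goal_calories <- 2000
  stated <- list(calories = 1900)
  rec <- make_record(prompt_id = cohort$id, item_names = "rice",
                     stated_totals = list(calories = 1900, protein = 10,
                                          fiber = 1, calcium = 20,
                                          phosphorus = 80, potassium = 50,
                                          sodium = 8))
  acc <- score_responses(list(rec), cohort, tab, tiny_mapping())
  expect_equal(nrow(acc), 7)
  # reference for 150 g rice: 150, 3, 1.5, 15, 75, 60, 7.5
  expect_equal(acc$reference[acc$nutrient == "phosphorus"], 75)
  expect_true(acc$external_accurate[acc$nutrient == "phosphorus"]) # 80/75
  expect_false(acc$external_accurate[acc$nutrient == "calcium"])   # 20/15
  expect_true(acc$external_accurate[acc$nutrient == "sodium"])     # 8/7.5
  expect_false(acc$external_accurate[acc$nutrient == "calories"])
  # internal: calories 1900 within 10% of 2000; minerals all under caps
  expect_true(acc$internal_accurate[acc$nutrient == "calories"])
  expect_true(all(acc$internal_accurate[acc$goal_type == "threshold"]))
})

test_that("missing stated values follow the missing policy", {
  tab <- tiny_reference_table()
  cohort <- simulate_cohort(cohort_config(n = 2, seed = 63))
  recs <- list(
    make_record("r1", cohort$id[1],
                stated_totals = list(calories = 150, protein = 3,
                                     fiber = 1.5, phosphorus = 75,
                                     potassium = 60, sodium = 7.5)),
    make_record("r2", cohort$id[2],
                stated_totals = list(calories = 150, protein = 3,
                                     fiber = 1.5, calcium = 15,
                                     phosphorus = 75, potassium = 60,
                                     sodium = 7.5)))
  acc_ex <- score_responses(recs, cohort, tab, tiny_mapping())
  ca <- acc_ex[acc_ex$nutrient == "calcium", ]
  expect_true(is.na(ca$external_accurate[ca$response_id == "r1"]))
  sum_ex <- accuracy_summary(acc_ex, "external")
  expect_equal(sum_ex$n_scorable[sum_ex$nutrient == "calcium"], 1)
  expect_equal(sum_ex$percent[sum_ex$nutrient == "calcium"], 100)

  cfg <- scoring_config(missing_policy = "count_inaccurate")
  acc_ct <- score_responses(recs, cohort, tab, tiny_mapping(), cfg)
  sum_ct <- accuracy_summary(acc_ct, "external")
  expect_equal(sum_ct$percent[sum_ct$nutrient == "calcium"], 50)
  # counting missing as inaccurate can never raise a percentage
  both <- dplyr::inner_join(sum_ex, sum_ct, by = c("model_id", "nutrient"),
                            suffix = c("_ex", "_ct"))
  ok <- !is.na(both$percent_ex) & !is.na(both$percent_ct)
  expect_true(all(both$percent_ct[ok] <= both$percent_ex[ok]))
})

test_that("widening the tolerance never lowers a percentage", {
  cohort <- simulate_cohort(cohort_config(n = 20, seed = 64))
  tab <- example_reference_table()
  synth <- synthesize_responses(cohort, tab,
                                realistic_error_model(),
                                models = c("m1", "m2"), seed = 65)
  narrow <- accuracy_summary(
    score_responses(synth$records, cohort, tab, synth$mapping,
                    scoring_config(tolerance = 0.10)), "external")
  wide <- accuracy_summary(
    score_responses(synth$records, cohort, tab, synth$mapping,
                    scoring_config(tolerance = 0.20)), "external")
  joined <- dplyr::inner_join(narrow, wide,
                              by = c("model_id", "nutrient"),
                              suffix = c("_n", "_w"))
  ok <- !is.na(joined$percent_n) & !is.na(joined$percent_w)
  expect_true(all(joined$percent_w[ok] >= joined$percent_n[ok]))
  expect_true(all(joined$percent_n[ok] >= 0 & joined$percent_n[ok] <= 100))
  # accounting identity: accurate + inaccurate + missing = all rows
  acc <- score_responses(synth$records, cohort, tab, synth$mapping)
  n_acc <- sum(acc$external_accurate, na.rm = TRUE)
  n_inacc <- sum(!acc$external_accurate, na.rm = TRUE)
  n_missing <- sum(is.na(acc$external_accurate))
  expect_equal(n_acc + n_inacc + n_missing, nrow(acc))
})

test_that("unjoinable responses are reported by id", {
  cohort <- simulate_cohort(cohort_config(n = 1, seed = 66))
  rec <- make_record(prompt_id = "GHOST")
  expect_error(score_responses(list(rec), cohort, tiny_reference_table(),
                               tiny_mapping()),
               "GHOST")
})

test_that("deviation summaries collapse to zero width for constant ratios", {
  tab <- tiny_reference_table()
  cohort <- simulate_cohort(cohort_config(n = 6, seed = 67))
  em <- response_error_model(bias = 0.8)
  synth <- synthesize_responses(cohort, tab, em, models = "m1", seed = 68)
  acc <- score_responses(synth$records, cohort, tab, synth$mapping)
  dev <- deviation_summary(acc)
  expect_equal(dev$pct_of_reference_mean, rep(80, nrow(dev)))
  expect_equal(dev$pct_of_reference_lo, dev$pct_of_reference_hi)
  # a single response per cell leaves the interval undefined, with warning
  acc1 <- score_responses(synth$records[1], cohort, tab, synth$mapping)
  expect_warning(dev1 <- deviation_summary(acc1), "fewer than 2")
  expect_true(all(is.na(dev1$pct_of_reference_lo)))
})
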