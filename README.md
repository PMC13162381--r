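# renalmeal

Simulation and concordance scoring for evaluating machine-generated
single-day meal plans for patients on maintenance hemodialysis.

End-stage kidney disease imposes tightly coupled dietary constraints —
calorie and protein targets to prevent protein-energy wasting alongside
daily ceilings on potassium, phosphorus, sodium, calcium and fluid.
Conversational AI assistants are increasingly asked for meal plans under
exactly these constraints, and evaluating them reproducibly requires
more than eyeballing transcripts. `renalmeal` provides the full
measurement pipeline for researchers doing that evaluation:

1. **Cohort simulation** — hypothetical hemodialysis patients drawn from
   distributions mirroring the US dialysis population, with
   individualized nutrition goals from guideline rules: calories at
   35 kcal/kg/day under age 60 and N(32.5, 1.25²) clipped to [30, 35]
   at 60+; protein at 1.2 g/kg/day (1.3 with protein-energy wasting);
   mineral maxima from clipped log-normals, e.g. sodium
   exp(N(log 2000, 0.1²)) clipped to [750, 2000] mg/day.
2. **Prompt rendering** — a fixed conversational, zero-shot prompt per
   patient, with every rounded goal value verbatim in the text.
3. **Reference lookup** — per-100 g food-composition tables merged with
   source priority (USDA > McCance–Widdowson > AUSNUT) and a frozen
   portion mapping from response items to table records.
4. **Synthetic responses** — structured meal-plan records with
   controllable per-nutrient multiplicative bias, log-normal noise,
   missingness, and goal-echoing behavior, standing in for live chatbot
   transcripts.
5. **Scoring** — *external* concordance (stated daily totals within
   ±10% of the reference, bounds inclusive) and *internal* concordance
   (±10% of target goals; at most 110% of threshold-type maxima), plus
   percent-of-reference and percent-deviation-from-goal summaries with
   95% CIs.
6. **Qualitative errors** — reviewer annotations across five usability
   categories aggregated by majority rule, and prevalence tables.
7. **Statistics** — paired Wilcoxon signed-rank comparison of
   macronutrient vs micronutrient concordance per response, and a
   rank-sum comparison of usability-error burden by cuisine preference.

See `vignettes/meal-plan-evaluation.Rmd` for the model, assumptions and
design decisions.

## Worked example

```r
library(renalmeal)

cohort <- simulate_cohort(cohort_config(n = 50, seed = 42))
cohort_summary(cohort)[c(1, 28:31), c("characteristic", "value")]
#>   characteristic      value
#> 1 Age in years        64 (13)
#> 2 Calcium (mg/day)    < 960 (59)
#> 3 Phosphorus (mg/day) < 882 (185)
#> 4 Potassium (mg/day)  < 2741 (302)
#> 5 Sodium (mg/day)     < 1944 (101)
```

Mean (SD) for continuous characteristics, n (%) for categorical ones;
the `<` marks daily maxima. The sodium cap averages ~1944 mg/day
because half of all draws clip at the 2000 mg guideline ceiling.

```r
res <- run_pipeline(pipeline_config(n = 50, seed = 42), out_dir = "results")

tidyr::pivot_wider(res$internal_summary[, c("model_id", "nutrient", "percent")],
                   names_from = nutrient, values_from = percent)
#>   model_id calories protein fiber calcium phosphorus potassium sodium
#> 1 model_A        14      10     6      60         23        52     67
#> 2 model_B        16      14     8      73         29        46     67
#> 3 model_C         8       6    10      73         23        49     69
#> 4 model_D        24       8     8      68         27        50     75

res$stats$macro_micro_internal[c("p_value", "macro_mean", "micro_mean")]
#> $p_value    8.07e-31
#> $macro_mean 0.110
#> $micro_mean 0.532

res$stats$cuisine$mean_errors
#>    with_preference without_preference
#>              1.239              0.652
```

Each cell is the integer percentage of that synthetic model's 50
responses whose stated daily total met the internal rule for that
nutrient. Under the default `realistic_error_model()` — biased low on
phosphorus and potassium with substantial noise — threshold-type
micronutrient caps are met far more often than point targets
(53% vs 11% of rows per response; p ≪ 0.001), and responses to
cuisine-preference prompts carry about twice the usability-error
burden, the qualitative pattern the framework is designed to measure.
Swap in `response_error_model(mode = "goal_driven")` to emulate
assistants that echo the prompt's numbers regardless of food content.

## Repository layout

- `R/` — implementation; `tests/testthat/` — unit, property and
  end-to-end tests (fixtures are built in code).
- `inst/extdata/food_composition_synthetic.csv` — the synthetic
  ~60-food reference fixture (realistic values, not for dietary use).
- `vignettes/meal-plan-evaluation.Rmd` — methods and design decisions.
- `scripts/acceptance.R` — see above.
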