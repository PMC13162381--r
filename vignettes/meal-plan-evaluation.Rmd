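---
title: "Evaluating machine-generated hemodialysis meal plans: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating machine-generated hemodialysis meal plans: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalmeal)
```

## The problem

Patients on maintenance hemodialysis must balance competing dietary
constraints: enough calories and protein to prevent protein-energy
wasting, but strict daily ceilings on potassium, phosphorus, sodium,
calcium and fluid. Conversational AI assistants are an obvious — and
risky — place patients might turn for meal plans. Evaluating such
assistants requires (i) realistic, guideline-concordant patient
scenarios, (ii) a standardized prompt, (iii) a trusted food-composition
reference, and (iv) explicit concordance rules. `renalmeal` implements
that evaluation framework end to end, replacing live chatbot calls with
a synthetic response generator whose error structure is controlled and
therefore testable.

## Cohort simulation

`simulate_cohort()` draws hypothetical patients from distributions
mirroring the US hemodialysis population: age $N(63, 14^2)$ years,
BMI $N(29.7, 1.8^2)$ kg/m², serum albumin $N(3.1, 0.3^2)$ g/dL, serum
phosphorus $N(5.0, 1.1^2)$ mg/dL, and Bernoulli prevalences for
comorbidities (hypertension 0.88, diabetes 0.58, heart failure 0.28),
protein-energy wasting (0.33), food insecurity (0.2615), fixed income
(0.82) and so on. Continuous draws are clipped to physiologic ranges
(age 18–95, BMI 15–45, albumin 1.5–5.0 g/dL, serum phosphorus 2–9
mg/dL) to prevent absurd tails at the stated SDs.

Nutrition goals follow per-kilogram guideline rules applied to a
**standardized (dosing) weight**:

* **Calories**: 35 kcal/kg/day under age 60; at 60+ a rate drawn from
  $N(32.5, 1.25^2)$ clipped to $[30, 35]$, honoring the 30–35
  kcal/kg/day guideline band.
* **Protein**: 1.2 g/kg/day, or 1.3 with protein-energy wasting.
* **Fiber**: target drawn from $N(22.5, 1.25^2)$ g/day.
* **Phosphorus maximum**: rate from $N(12, 1)$ mg/kg/day when serum
  phosphorus exceeds 5.5 mg/dL (strictly), else $N(14, 1)$.
* **Sodium, calcium, potassium maxima**: $\exp(N(\mu, \sigma^2))$ with
  $(\mu, \sigma) = (\log 2000, 0.1)$, $(\log 1000, 0.1)$,
  $(\log 2730, 0.1)$, clipped to $[750, 2000]$, $[600, 1000]$ and
  $[1800, 3120]$ mg/day respectively.

### Truncation means clipping

"Truncated" log-normals are implemented by **clipping** — draws outside
the bounds are set to the bound — rather than by rejection resampling.
The bounds here are guideline ceilings that are themselves sensible
prescriptions: under clipping, half of all sodium maxima are exactly
2000 mg/day, and the population mean of the clipped draw is
$\approx 1925$ mg/day, matching the observed scale of simulated
cohorts; rejection sampling would instead centre the sodium maximum
near 1850 mg/day, several standard errors away. The same choice
reproduces the calcium maximum mean ($\approx 962$ mg/day).

### Standardized weight

Per-kilogram prescriptions in dialysis are scaled by a normalized
dosing weight, not raw dry weight, but there is no universal formula.
The default here is the adjusted body weight convention
$\mathrm{aBW} = \mathrm{IBW} + 0.25\,(\mathrm{dry} - \mathrm{IBW})$,
with ideal body weight from the Devine formula using the patient's
sampled sex and height (sex-specific heights $N(1.76, 0.07^2)$ m for
men, $N(1.62, 0.07^2)$ m for women; dry weight is
$\mathrm{BMI} \times \mathrm{height}^2$). A `weight_basis = "dry"`
mode is provided; the adjustment factor is configurable. No choice of
factor makes all published goal summaries simultaneously consistent,
so the convention is fixed once and documented rather than tuned.

### Quantities the guidelines do not pin down

A few generator defaults are conventions chosen once, each matching
either a published summary or ordinary practice:

* **Fluid maximum**: no distribution is prescribed; the default
  $N(1172, 99^2)$ mL clipped to $[800, 1500]$ matches the observed
  summary scale of simulated cohorts and is config-overridable.
* **Budget**: normal with mean \$12/day for fixed-income patients and
  \$15/day otherwise; the within-group SD (not separately published) is
  1.2, chosen so the pooled cohort SD is about 1.64 at 82% fixed
  income.
* **Rounding**: goals are rounded to prompt granularity — calories,
  mineral maxima and fluid to the nearest 50, protein and fiber to
  whole grams, budgets to \$0.50 — because that is the precision a
  dietitian's instruction (and hence the prompt) carries. Rounded
  values are used both in the prompt and in internal-concordance
  scoring.
* **Cuisine list**: 21 named cuisines with equal probability, half of
  patients having no preference.

## The prompt

`render_prompt()` produces the fixed conversational prompt: first
person, demographics and dialysis schedule, the dietitian's goals, lab
values, then one sentence per constraint (celiac, allergies, cuisine
preference, budget, food insecurity, vegetarianism, comorbidities in
the fixed order heart failure → high blood pressure → diabetes), and a
fixed three-sentence closing instruction requesting per-meal and daily
nutrient lists for a single day. Affirmative variants of the
conditional sentences ("I have Celiac disease.", "I am allergic to
fish and peanut.", "I prefer Thai food.") are conventions of this
package — only the negative forms are fixed by the worked example —
and every rounded goal value appears verbatim in the text, which the
tests verify by regex round-trip.

## Reference table and portion mapping

External concordance needs a food-composition reference. The package
reads per-100 g CSV tables from three sources (USDA,
McCance–Widdowson, AUSNUT) and merges them with source priority
USDA > MW > AUSNUT on normalized food names (lowercase, parentheticals
and punctuation stripped). A roughly sixty-food **synthetic** fixture
ships with the package for tests and examples; its values are
realistic but invented, and it stands in for the proprietary merged
database.

Matching response items to table records is a human judgment in the
original workflow; here it is a frozen, auditable `PortionMapping`
file (`item_name, food_id, grams`), with `suggest_mapping()` offering
exact normalized-name candidates only as a convenience. Items with no
mapping (composite foods such as "Chinese bun") are excluded from
reference totals and counted; a response whose unmatched fraction
exceeds 25% (configurable) is unscorable for external concordance
rather than silently misscored.

## Synthetic responses

Because real chatbot transcripts are not deposited, `synthesize_responses()`
generates structured stand-ins: 3–5 meals of items drawn from the
reference table with log-uniform portions in $[30, 400]$ g, true
totals computed from the table, and stated values perturbed by a
`response_error_model()`:

* per-nutrient multiplicative **bias** $b$;
* log-normal **noise** $e^{\varepsilon}$, $\varepsilon \sim N(0,
  \sigma^2)$, drawn once per response × nutrient and shared across that
  response's items — so stated item values always sum to the stated
  daily totals, and the stated/reference ratio is exactly
  $b\,e^{\varepsilon}$. That makes the expected external concordance
  available in closed form,
  $\Phi\!\big(\tfrac{\ln 1.1 - \ln b}{\sigma}\big) -
  \Phi\!\big(\tfrac{\ln 0.9 - \ln b}{\sigma}\big)$,
  which the tests verify by simulation;
* per-nutrient **missingness** (a nutrient vanishes from all stated
  values of a response);
* a **goal_driven** mode in which stated totals track the prompt's
  goals instead of the food content — the behavior implied when
  internal concordance far exceeds external concordance;
* an optional **sloppy-sum** perturbation that breaks totals/item-sum
  consistency, to exercise the scorer's `totals_policy`.

`realistic_error_model()` bundles defaults emulating the direction of
observed chatbot behavior: phosphorus and potassium biased low (0.72,
0.78), $\sigma = 0.25$ (about 30% external concordance for an unbiased
nutrient), 4% micronutrient missingness, and qualitative-error
probabilities whose preference/no-preference mixture yields about 1.0
vs 0.48 expected usability errors per response. These are properties
of the synthetic stand-in, not estimates of any particular product.

What the generator deliberately does **not** emulate: free-text
formatting, arithmetic slips inside a response (except via sloppy-sum),
item-level idiosyncrasies (all items of a response share one error
factor per nutrient), menu plausibility, or allergy/cuisine adherence.
Passing tests therefore demonstrate that the *measurement pipeline* is
correct and calibrated, not that any real assistant behaves this way.

## Scoring rules

For each response and each of the seven nutrients (calories, protein,
fiber; calcium, phosphorus, potassium, sodium):

* **External concordance**: stated daily total within ±10% of the
  reference total, bounds inclusive (a ratio of exactly 0.9 or 1.1
  is concordant; "within 10%" carries no boundary semantics, and the
  inclusive reading is the generous one).
* **Internal concordance**: for targets, the same ±10% band around the
  prompt goal — by construction the identical predicate to the
  external rule, which a property test asserts; for thresholds (the
  mineral maxima), any value at or below 110% of the cap, with no
  lower bound (a clinically odd 100 mg sodium day is still "within
  instructions" under the stated rule).
* A zero reference is concordant only with a zero stated value.
* Missing stated values are excluded from denominators by default
  (missingness is reported separately); `count_inaccurate` is
  available and can only lower percentages, which is tested as an
  invariant.
* Stated daily totals are scored when present (`totals_policy =
  "stated_totals"`); re-summing item values is the alternative.

Summaries report integer percentages per model × nutrient (cells with
no scorable rows are `NA`, never 0), mean percent-of-reference, mean
signed and mean absolute percent deviation from goal, each with
t-based 95% confidence intervals over responses (the CI method for
such figures is not otherwise specified).

## Qualitative errors and statistics

Reviewer annotations (five binary categories: hallucination, technical
error, atypical recommendation, vague instruction, composite food
error) aggregate by majority rule — strictly more than half of the
reviewers. With an even panel a tie resolves to "not flagged" with a
warning; the standard three-reviewer panel cannot tie.

Two nonparametric comparisons are provided, both via
`stats::wilcox.test` behind the module surface and both cross-checked
against brute-force enumeration of the exact null in the tests:

* `macro_micro_test()`: per response, the proportion of concordant
  macronutrient rows vs micronutrient rows, compared by a paired
  two-sided Wilcoxon signed-rank test (zeros dropped; exact null at
  ≤ 25 informative untied pairs, tie-corrected normal approximation
  with continuity correction otherwise). The pairing unit is one
  response; the published description is ambiguous between response-,
  nutrient- and model-level pairing, so a pooled cluster-ignorant
  rank-sum mode is provided as a sensitivity analysis.
* `cuisine_error_test()`: per-response consensus error counts,
  compared between prompts with and without a cuisine preference by a
  two-sided rank-sum test.

## Pipeline, determinism and problem sizes

`run_pipeline()` chains every stage under one root seed that spawns
per-stage child seeds, so a stage can be rerun without disturbing the
draws of the others; the manifest records seeds, a config hash, and
record counts that must reconcile across stage boundaries. Identical
config and seed give byte-identical output files.

Tests run the full evaluation at its study size (50 prompts × 4
synthetic models = 200 responses) in a few seconds; distributional
checks use $10^4$–$2\times10^5$ draws, sized so Monte-Carlo standard
errors are far below the tolerances being asserted while the whole
suite stays under a minute. `scripts/acceptance.R` recomputes the
cohort summary quantities on a 100,000-patient cohort.

## Known limitations

* The generator's realism is structural, not behavioral: it cannot
  certify any actual assistant, only the measurement of one.
* The synthetic food table is small and invented; real evaluations
  must supply real composition tables and a curated portion mapping.
* Fluid and budget scoring are out of scope (stated values for them
  are neither generated nor scored), mirroring the exclusions of the
  evaluation design the package implements.
* Goal rules encode one reading of the guidelines (e.g. the strict
  inequality at serum phosphorus 5.5 mg/dL, clipping rather than
  resampling); both are configurable where a different reading is
  defensible.
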