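#' Error model for synthetic meal-plan responses
#'
#' Describes the error structure injected into synthetic responses, which
#' stand in for live chatbot transcripts: a multiplicative per-nutrient
#' bias, log-normal noise shared across the items of a response, a
#' per-nutrient probability that a nutrient's stated values are omitted
#' entirely, and per-category probabilities of the qualitative usability
#' errors (separately for prompts with and without a cuisine preference).
#'
#' With `mode = "reference_driven"` the stated values track the true food
#' content of the plan: each stated item value equals the table-derived
#' value times `bias[nutrient] * exp(eps)` with one
#' `eps ~ N(0, noise_sigma^2)` drawn per response and nutrient. With
#' `mode = "goal_driven"` stated values are scaled so that the stated
#' daily total equals `goal * exp(eps)`, emulating a model that echoes the
#' prompt's numbers regardless of what the food actually contains.
#' Either way stated item values sum exactly to the stated daily totals
#' (set `sloppy_sum_sigma > 0` to perturb the daily totals independently
#' and break that consistency on purpose).
#'
#' @param bias Multiplicative per-nutrient bias (> 0); scalar or named
#'   vector over the seven nutrients.
#' @param noise_sigma Log-scale noise SD (>= 0); scalar or named vector.
#' @param missing_prob Per-nutrient probability that the nutrient is
#'   omitted from all stated values of a response.
#' @param mode `"reference_driven"` or `"goal_driven"` (see above).
#' @param qualitative_error_probs Named vector over
#'   [qualitative_categories()]: probability a response truly carries each
#'   error, for prompts without a cuisine preference.
#' @param cuisine_error_probs The same, for prompts with a cuisine
#'   preference.
#' @param reviewer_flip_prob Probability that an individual reviewer's
#'   annotation disagrees with the latent truth.
#' @param sloppy_sum_sigma Log-scale SD of an optional independent
#'   perturbation of the stated daily totals (default 0 = totals are the
#'   exact sum of item values).
#' @return A list of class `response_error_model`. The default is the
#'   identity model: unbiased, noiseless, nothing missing, no qualitative
#'   errors.
#' @seealso [realistic_error_model()] for a configuration emulating
#'   observed chatbot behavior.
#' @export
response_error_model <- function(bias = 1, noise_sigma = 0,
                                 missing_prob = 0,
                                 mode = c("reference_driven", "goal_driven"),
                                 qualitative_error_probs = 0,
                                 cuisine_error_probs = qualitative_error_probs,
                                 reviewer_flip_prob = 0,
                                 sloppy_sum_sigma = 0) {
  mode <- match.arg(mode)
  qual_param <- function(x, what) {
    out <- setNames(rep(0, length(QUAL_CATEGORIES)), QUAL_CATEGORIES)
    if (is.null(names(x))) {
      out[] <- x
    } else {
      bad <- setdiff(names(x), QUAL_CATEGORIES)
      if (length(bad) > 0) stop("unknown categories in ", what, ": ",
                                paste(bad, collapse = ", "), call. = FALSE)
      out[names(x)] <- x
    }
    check_prob(out, what)
    out
  }
  em <- list(
    bias = nutrient_param(bias, 1, "bias"),
    noise_sigma = nutrient_param(noise_sigma, 0, "noise_sigma"),
    missing_prob = nutrient_param(missing_prob, 0, "missing_prob"),
    mode = mode,
    qualitative_error_probs = qual_param(qualitative_error_probs,
                                         "qualitative_error_probs"),
    cuisine_error_probs = qual_param(cuisine_error_probs,
                                     "cuisine_error_probs"),
    reviewer_flip_prob = reviewer_flip_prob,
    sloppy_sum_sigma = sloppy_sum_sigma)
  if (any(em$bias <= 0)) stop("bias must be positive", call. = FALSE)
  if (any(em$noise_sigma < 0)) stop("noise_sigma must be non-negative",
                                    call. = FALSE)
  check_prob(em$missing_prob, "missing_prob")
  check_prob(em$reviewer_flip_prob, "reviewer_flip_prob")
  structure(em, class = "response_error_model")
}

#' Error model emulating observed chatbot meal-planning behavior
#'
#' A [response_error_model()] whose parameters reproduce the qualitative
#' pattern reported for commercial chatbots: phosphorus and potassium
#' content underestimated, moderate log-scale noise (about 30% external
#' concordance for an unbiased nutrient), occasional omission of
#' micronutrient values, and qualitative usability errors that are about
#' twice as frequent for prompts carrying a cuisine preference (roughly
#' 1.0 vs 0.48 expected errors per response).
#'
#' @param ... Overrides passed on to [response_error_model()].
#' @return A `response_error_model`.
#' @export
realistic_error_model <- function(...) {
  defaults <- list(
    bias = c(calories = 0.97, protein = 1.00, fiber = 0.90,
             calcium = 0.92, phosphorus = 0.72, potassium = 0.78,
             sodium = 0.88),
    noise_sigma = 0.25,
    missing_prob = c(calcium = 0.04, phosphorus = 0.04,
                     potassium = 0.04, sodium = 0.04),
    qualitative_error_probs = c(hallucination = 0,
                                technical_error = 0.015,
                                atypical_recommendation = 0.062,
                                vague_instruction = 0.151,
                                composite_food_error = 0.252),
    cuisine_error_probs = c(hallucination = 0,
                            technical_error = 0.032,
                            atypical_recommendation = 0.128,
                            vague_instruction = 0.314,
                            composite_food_error = 0.526),
    reviewer_flip_prob = 0.1)
  args <- utils::modifyList(defaults, list(...))
  do.call(response_error_model, args)
}

MEAL_NAMES <- c("Breakfast", "Lunch", "Dinner", "Snack 1", "Snack 2")

#' Synthesize structured meal-plan responses for a cohort
#'
#' Generates, for every patient and every synthetic model profile, one
#' structured meal-plan response: 3--5 meals of items drawn from the
#' reference table with log-uniform portion sizes, true nutrient content
#' computed from the table, and stated values perturbed according to the
#' error model (see [response_error_model()]). The generator also emits
#' the portion mapping that resolves every generated item name back to its
#' table record, so synthetic batches are fully scorable.
#'
#' @param cohort A tibble from [simulate_cohort()].
#' @param table A merged reference table.
#' @param error_model A [response_error_model()], or a named list of one
#'   model per entry of `models` to give each synthetic model its own
#'   error structure.
#' @param models Character vector of synthetic model identifiers.
#' @param seed Optional integer seed.
#' @param meals_range,items_range Integer ranges for the number of meals
#'   per plan and items per meal.
#' @param portion_range Portion-size range in grams; portions are drawn
#'   log-uniformly and rounded to whole grams.
#' @return A list with `records` (list of meal-plan records) and `mapping`
#'   (tibble `item_name, food_id, grams`).
#' @export
synthesize_responses <- function(cohort, table,
                                 error_model = response_error_model(),
                                 models = paste0("model_",
                                                 c("A", "B", "C", "D")),
                                 seed = NULL,
                                 meals_range = c(3, 5),
                                 items_range = c(2, 4),
                                 portion_range = c(30, 400)) {
  if (nrow(table) == 0) stop("reference table is empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(error_model, "response_error_model")) {
    error_model <- setNames(rep(list(error_model), length(models)), models)
  }
  if (!all(models %in% names(error_model))) {
    stop("error_model must cover every model id", call. = FALSE)
  }

  records <- list()
  map_rows <- list()
  k <- 0
  for (i in seq_len(nrow(cohort))) {
    patient <- cohort[i, ]
    for (model_id in models) {
      k <- k + 1
      em <- error_model[[model_id]]
      rec <- synthesize_one(patient, table, em, model_id,
                            meals_range, items_range, portion_range)
      records[[k]] <- rec$record
      map_rows[[k]] <- rec$mapping
    }
  }
  mapping <- dplyr::distinct(dplyr::bind_rows(map_rows))
  list(records = records, mapping = mapping)
}

synthesize_one <- function(patient, table, em, model_id,
                           meals_range, items_range, portion_range) {
  n_meals <- sample(meals_range[1]:meals_range[2], 1)
  per100 <- as.matrix(table[REF_NUTRIENT_COLUMNS])
  colnames(per100) <- NUTRIENTS

  ## response-level multiplicative error, shared across the response's
  ## items so stated/true ratios are exactly bias * exp(eps) per nutrient
  eps <- rnorm(length(NUTRIENTS), 0, em$noise_sigma)
  missing <- rbinom(length(NUTRIENTS), 1, em$missing_prob) == 1
  names(eps) <- names(missing) <- NUTRIENTS

  meal_items <- lapply(seq_len(n_meals), function(m) {
    n_items <- sample(items_range[1]:items_range[2], 1)
    rows <- sample(nrow(table), n_items, replace = FALSE)
    grams <- round(exp(runif(n_items, log(portion_range[1]),
                             log(portion_range[2]))))
    list(rows = rows, grams = grams)
  })

  all_rows <- unlist(lapply(meal_items, `[[`, "rows"))
  all_grams <- unlist(lapply(meal_items, `[[`, "grams"))
  true_items <- per100[all_rows, , drop = FALSE] * all_grams / 100
  true_totals <- colSums(true_items)

  factor <- if (em$mode == "reference_driven") {
    em$bias * exp(eps)
  } else {
    goals <- vapply(GOAL_COLUMNS, function(col) patient[[col]], numeric(1))
    names(goals) <- NUTRIENTS
    target <- goals * exp(eps)
    ifelse(true_totals > 0, target / true_totals, 0)
  }
  stated_items <- sweep(true_items, 2, factor, `*`)
  stated_items[, missing] <- NA_real_

  item_index <- 0
  meals <- lapply(seq_len(n_meals), function(m) {
    mi <- meal_items[[m]]
    items <- lapply(seq_along(mi$rows), function(j) {
      item_index <<- item_index + 1
      stated <- as.list(stated_items[item_index, ])
      stated <- stated[!is.na(unlist(stated))]
      list(item_name = sprintf("%s, %d g", table$name[mi$rows[j]],
                               mi$grams[j]),
           portion_text = sprintf("%d g", mi$grams[j]),
           stated = stated)
    })
    list(meal_name = MEAL_NAMES[m], items = items)
  })

  totals <- colSums(stated_items)
  if (em$sloppy_sum_sigma > 0) {
    totals <- totals * exp(rnorm(length(totals), 0, em$sloppy_sum_sigma))
  }
  stated_daily_totals <- as.list(totals)
  stated_daily_totals <- stated_daily_totals[!is.na(unlist(stated_daily_totals))]

  record <- list(
    response_id = sprintf("%s-%s", patient$id, model_id),
    prompt_id = patient$id,
    model_id = model_id,
    meals = meals,
    stated_daily_totals = stated_daily_totals)

  mapping <- tibble::tibble(
    item_name = sprintf("%s, %d g", table$name[all_rows], all_grams),
    food_id = table$food_id[all_rows],
    grams = all_grams)

  list(record = record, mapping = mapping)
}

#' Read and write structured meal-plan responses as JSON lines
#'
#' One JSON object per line with fields `response_id`, `prompt_id`,
#' `model_id`, `meals` (each with `meal_name` and `items`; each item has
#' `item_name`, `portion_text` and a `stated` nutrient object whose fields
#' are individually optional), and `stated_daily_totals`. Reading
#' validates each record and reports the index of any violation; stated
#' values must be non-negative, and every plan must contain at least one
#' meal with at least one item.
#'
#' @param records A list of meal-plan records.
#' @param path File path.
#' @return `read_responses()` returns the validated list of records;
#'   `write_responses()` returns `path` invisibly.
#' @export
write_responses <- function(records, path) {
  lines <- vapply(records, function(rec) {
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  records <- lapply(seq_along(lines), function(i) {
    rec <- jsonlite::fromJSON(lines[i], simplifyVector = FALSE)
    validate_response(rec, i)
  })
  records
}

validate_response <- function(rec, index = NA) {
  where <- if (is.na(index)) "" else paste0(" (record ", index, ")")
  for (field in c("response_id", "prompt_id", "model_id", "meals")) {
    if (is.null(rec[[field]])) {
      stop("missing required field ", field, where, call. = FALSE)
    }
  }
  if (length(rec$meals) < 1) stop("plan has no meals", where, call. = FALSE)
  check_stated <- function(stated, ctx) {
    if (is.null(stated)) return(invisible(NULL))
    bad <- setdiff(names(stated), NUTRIENTS)
    if (length(bad) > 0) {
      stop("unknown nutrient(s) ", paste(bad, collapse = ", "),
           " in ", ctx, where, call. = FALSE)
    }
    vals <- unlist(stated)
    if (any(!is.na(vals) & vals < 0)) {
      stop("negative stated value in ", ctx, where, call. = FALSE)
    }
  }
  for (meal in rec$meals) {
    if (is.null(meal$items) || length(meal$items) < 1) {
      stop("meal without items", where, call. = FALSE)
    }
    for (item in meal$items) {
      if (is.null(item$item_name)) {
        stop("item without item_name", where, call. = FALSE)
      }
      check_stated(item$stated, paste0("item '", item$item_name, "'"))
    }
  }
  check_stated(rec$stated_daily_totals, "stated_daily_totals")
  rec
}

#' Compact metadata for a list of responses
#'
#' @param records A list of meal-plan records.
#' @return A tibble `response_id, prompt_id, model_id`.
#' @export
responses_meta <- function(records) {
  dplyr::bind_rows(lapply(records, function(rec) {
    tibble::tibble(response_id = rec$response_id,
                   prompt_id = rec$prompt_id,
                   model_id = rec$model_id)
  }))
}

## Long tibble of stated daily totals per response x nutrient.
## totals_policy "stated_totals" reads the record's stated_daily_totals;
## "sum_items" re-sums the per-item stated values.
stated_totals_all <- function(records, totals_policy = "stated_totals") {
  dplyr::bind_rows(lapply(records, function(rec) {
    stated <- setNames(rep(NA_real_, length(NUTRIENTS)), NUTRIENTS)
    if (totals_policy == "stated_totals" &&
        !is.null(rec$stated_daily_totals)) {
      vals <- unlist(rec$stated_daily_totals)
      stated[names(vals)] <- vals
    } else {
      for (meal in rec$meals) {
        for (item in meal$items) {
          vals <- unlist(item$stated)
          if (length(vals) > 0) {
            nm <- names(vals)
            stated[nm] <- ifelse(is.na(stated[nm]), vals,
                                 stated[nm] + vals)
          }
        }
      }
    }
    tibble::tibble(response_id = rec$response_id,
                   prompt_id = rec$prompt_id,
                   model_id = rec$model_id,
                   nutrient = NUTRIENTS,
                   stated = as.numeric(stated))
  }))
}
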