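#' Scoring configuration
#'
#' @param tolerance Relative tolerance for target-type concordance
#'   (default 0.10: stated values within ±10% of the reference or goal
#'   are concordant).
#' @param threshold_cap Multiplier for threshold-type goals (daily
#'   maxima): stated values at or below `threshold_cap * goal` are
#'   concordant. Defaults to `1 + tolerance` (110%).
#' @param missing_policy What a missing stated value contributes:
#'   `"exclude"` (default; the row is dropped from denominators) or
#'   `"count_inaccurate"`.
#' @param totals_policy Which daily figure is scored: the response's
#'   `"stated_totals"` (default) or the `"sum_items"` re-sum of per-item
#'   stated values.
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(tolerance = 0.10, threshold_cap = NULL,
                           missing_policy = c("exclude", "count_inaccurate"),
                           totals_policy = c("stated_totals", "sum_items")) {
  if (!is.finite(tolerance) || tolerance <= 0) {
    stop("tolerance must be positive", call. = FALSE)
  }
  threshold_cap <- threshold_cap %||% (1 + tolerance)
  if (threshold_cap < 1) stop("threshold_cap must be at least 1",
                              call. = FALSE)
  structure(list(tolerance = tolerance, threshold_cap = threshold_cap,
                 missing_policy = match.arg(missing_policy),
                 totals_policy = match.arg(totals_policy)),
            class = "scoring_config")
}

## relative slack that makes the interval bounds robust to floating-point
## representation of e.g. 1.1 * 90
flag_eps <- function(x) 1e-9 * pmax(abs(x), 1)

#' External concordance flag
#'
#' A stated daily value is externally concordant when it lies within the
#' tolerance band around the reference-database value:
#' `stated in [(1 - tol) * reference, (1 + tol) * reference]`, bounds
#' inclusive. A zero reference is concordant only with a zero stated
#' value.
#'
#' @param stated,reference Non-negative amounts (vectors recycle).
#' @param config A [scoring_config()].
#' @return Logical vector; `NA` where `stated` is `NA`.
#' @examples
#' external_flag(25, 90)   # far outside +/-10% of 90
#' external_flag(99, 90)   # ratio exactly 1.1: concordant
#' @export
external_flag <- function(stated, reference, config = scoring_config()) {
  if (any(!is.na(stated) & stated < 0) || any(!is.na(reference) &
                                              reference < 0)) {
    stop("stated and reference values must be non-negative", call. = FALSE)
  }
  lo <- reference * (1 - config$tolerance)
  hi <- reference * (1 + config$tolerance)
  eps <- flag_eps(reference)
  out <- stated >= lo - eps & stated <= hi + eps
  out[!is.na(reference) & reference == 0] <-
    (stated[!is.na(reference) & reference == 0] == 0)
  out
}

#' Internal concordance flag
#'
#' For target-type goals (calories, protein, fiber) a stated value is
#' internally concordant when within the tolerance band around the goal —
#' the same interval predicate as [external_flag()]. For threshold-type
#' goals (the mineral and fluid maxima) any stated value at or below
#' `threshold_cap` times the goal (110% by default) is concordant, with
#' no lower bound.
#'
#' @param stated Non-negative amounts.
#' @param goal Positive goal values.
#' @param goal_type `"target"` or `"threshold"` (recycled).
#' @param config A [scoring_config()].
#' @return Logical vector; `NA` where `stated` is `NA`.
#' @examples
#' internal_flag(1800, 2000, "target")     # exactly 90% of goal: concordant
#' internal_flag(2200, 2000, "threshold")  # exactly 110% of cap: concordant
#' internal_flag(2201, 2000, "threshold")
#' @export
internal_flag <- function(stated, goal, goal_type,
                          config = scoring_config()) {
  if (any(!is.na(stated) & stated < 0)) {
    stop("stated values must be non-negative", call. = FALSE)
  }
  if (any(is.na(goal) | goal <= 0)) {
    stop("goal values must be positive", call. = FALSE)
  }
  bad <- setdiff(unique(goal_type), c("target", "threshold"))
  if (length(bad) > 0) {
    stop("unknown goal_type: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- max(length(stated), length(goal), length(goal_type))
  stated <- rep_len(stated, n)
  goal <- rep_len(goal, n)
  goal_type <- rep_len(goal_type, n)
  eps <- flag_eps(goal)
  ifelse(goal_type == "target",
         stated >= goal * (1 - config$tolerance) - eps &
           stated <= goal * (1 + config$tolerance) + eps,
         stated <= goal * config$threshold_cap + eps)
}

#' Score a batch of responses against reference and goals
#'
#' Builds the concordance table: one row per response and scored
#' nutrient, carrying the stated daily value (per `totals_policy`), the
#' reference-table total, the prompt goal, both concordance flags, the
#' stated value as a percentage of the reference, and the percent
#' deviation from the goal. External flags are `NA` for responses whose
#' unmapped-item fraction makes them unscorable (see
#' [reference_totals_all()]); missing stated values propagate per
#' `missing_policy`.
#'
#' @param records A list of meal-plan records.
#' @param cohort The cohort tibble the prompts came from.
#' @param table A merged reference table.
#' @param mapping Portion mapping for the records.
#' @param config A [scoring_config()].
#' @return A tibble with columns `response_id, prompt_id, model_id,
#'   nutrient, stated, reference, goal, goal_type, scorable_external,
#'   external_accurate, internal_accurate, pct_of_reference,
#'   pct_dev_from_goal`.
#' @export
score_responses <- function(records, cohort, table, mapping,
                            config = scoring_config()) {
  stated <- stated_totals_all(records, config$totals_policy)
  unjoined <- setdiff(unique(stated$prompt_id), cohort$id)
  if (length(unjoined) > 0) {
    stop("responses reference unknown prompt id(s): ",
         paste(unjoined, collapse = ", "), call. = FALSE)
  }
  refs <- reference_totals_all(records, mapping, table)

  goals_long <- cohort |>
    dplyr::select("id", dplyr::all_of(unname(GOAL_COLUMNS))) |>
    tidyr::pivot_longer(-"id", names_to = "goal_column",
                        values_to = "goal") |>
    dplyr::mutate(
      nutrient = names(GOAL_COLUMNS)[match(.data$goal_column,
                                           GOAL_COLUMNS)],
      goal_type = unname(GOAL_TYPES[.data$nutrient])) |>
    dplyr::select(prompt_id = "id", "nutrient", "goal", "goal_type")

  acc <- stated |>
    dplyr::left_join(refs, by = c("response_id", "nutrient")) |>
    dplyr::left_join(goals_long, by = c("prompt_id", "nutrient")) |>
    dplyr::mutate(
      external_accurate = ifelse(.data$scorable_external,
                                 external_flag(.data$stated,
                                               .data$reference, config),
                                 NA),
      internal_accurate = internal_flag(.data$stated, .data$goal,
                                        .data$goal_type, config),
      pct_of_reference = ifelse(.data$reference > 0,
                                100 * .data$stated / .data$reference,
                                NA_real_),
      pct_dev_from_goal = 100 * (.data$stated - .data$goal) / .data$goal)

  if (config$missing_policy == "count_inaccurate") {
    miss <- is.na(acc$stated)
    acc$external_accurate[miss & acc$scorable_external] <- FALSE
    acc$internal_accurate[miss] <- FALSE
  }
  dplyr::select(acc, "response_id", "prompt_id", "model_id", "nutrient",
                "stated", "reference", "goal", "goal_type",
                "scorable_external", "external_accurate",
                "internal_accurate", "pct_of_reference",
                "pct_dev_from_goal")
}

#' Percent-concordant summary by model and nutrient
#'
#' @param accuracy A tibble from [score_responses()].
#' @param kind `"external"` or `"internal"`.
#' @return A tibble `model_id, nutrient, n_scorable, n_accurate, percent`
#'   with `percent` the integer-rounded percentage of scorable rows that
#'   are concordant, and `NA` (never 0) where no row is scorable.
#' @export
accuracy_summary <- function(accuracy, kind = c("external", "internal")) {
  kind <- match.arg(kind)
  if (nrow(accuracy) == 0) stop("accuracy table is empty", call. = FALSE)
  col <- paste0(kind, "_accurate")
  accuracy |>
    dplyr::group_by(.data$model_id, .data$nutrient) |>
    dplyr::summarise(
      n_scorable = sum(!is.na(.data[[col]])),
      n_accurate = sum(.data[[col]], na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(
      percent = ifelse(.data$n_scorable == 0, NA_real_,
                       round(100 * .data$n_accurate / .data$n_scorable)),
      nutrient = factor(.data$nutrient, levels = NUTRIENTS)) |>
    dplyr::arrange(.data$model_id, .data$nutrient) |>
    dplyr::mutate(nutrient = as.character(.data$nutrient))
}

t_ci <- function(x, level = 0.95) {
  x <- x[!is.na(x)]
  n <- length(x)
  m <- mean(x)
  if (n < 2) return(c(mean = m, lo = NA_real_, hi = NA_real_, n = n))
  half <- qt(1 - (1 - level) / 2, n - 1) * sd(x) / sqrt(n)
  c(mean = m, lo = m - half, hi = m + half, n = n)
}

#' Deviation summary with 95% confidence intervals
#'
#' Per model and nutrient: the mean stated value as a percentage of the
#' reference, the mean signed percent deviation from the prompt goal, and
#' the mean absolute percent deviation from the goal, each with a t-based
#' 95% confidence interval over responses. Cells with fewer than two
#' scorable responses get `NA` intervals with a warning.
#'
#' @param accuracy A tibble from [score_responses()].
#' @param level Confidence level (default 0.95).
#' @return A tibble with one row per model and nutrient.
#' @export
deviation_summary <- function(accuracy, level = 0.95) {
  if (nrow(accuracy) == 0) stop("accuracy table is empty", call. = FALSE)
  out <- accuracy |>
    dplyr::group_by(.data$model_id, .data$nutrient) |>
    dplyr::summarise(
      n_ref = sum(!is.na(.data$pct_of_reference)),
      pct_of_reference_mean = mean(.data$pct_of_reference, na.rm = TRUE),
      pct_of_reference_lo = t_ci(.data$pct_of_reference, level)[["lo"]],
      pct_of_reference_hi = t_ci(.data$pct_of_reference, level)[["hi"]],
      n_goal = sum(!is.na(.data$pct_dev_from_goal)),
      pct_dev_from_goal_mean = mean(.data$pct_dev_from_goal, na.rm = TRUE),
      pct_dev_from_goal_lo = t_ci(.data$pct_dev_from_goal, level)[["lo"]],
      pct_dev_from_goal_hi = t_ci(.data$pct_dev_from_goal, level)[["hi"]],
      abs_dev_from_goal_mean = mean(abs(.data$pct_dev_from_goal),
                                    na.rm = TRUE),
      abs_dev_from_goal_lo = t_ci(abs(.data$pct_dev_from_goal),
                                  level)[["lo"]],
      abs_dev_from_goal_hi = t_ci(abs(.data$pct_dev_from_goal),
                                  level)[["hi"]],
      .groups = "drop")
  if (any(out$n_ref < 2 | out$n_goal < 2)) {
    warning("some cells have fewer than 2 scorable responses; ",
            "their confidence intervals are omitted", call. = FALSE)
  }
  out
}
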