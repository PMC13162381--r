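#' Paired comparison of macronutrient vs micronutrient concordance
#'
#' For each response, computes the proportion of scorable macronutrient
#' rows (calories, protein, fiber) and micronutrient rows (calcium,
#' phosphorus, potassium, sodium) that are concordant, then compares the
#' paired per-response proportions with a two-sided Wilcoxon signed-rank
#' test (zero differences dropped per Wilcoxon's convention; exact null
#' at 25 or fewer informative pairs when ties permit, otherwise the
#' tie-corrected normal approximation with continuity correction).
#'
#' The pairing unit is one response. `unit = "pooled"` instead treats
#' every (response, nutrient) flag as an independent 0/1 observation and
#' runs an unpaired rank-sum comparison — a cluster-ignorant sensitivity
#' analysis.
#'
#' @param accuracy A tibble from [score_responses()].
#' @param kind `"internal"` or `"external"` concordance.
#' @param unit `"response"` (paired, default) or `"pooled"`.
#' @return A list: `statistic`, `p_value`, `n_pairs` (informative pairs,
#'   or group sizes when pooled), `macro_mean`, `micro_mean`, `method`.
#' @export
macro_micro_test <- function(accuracy, kind = c("internal", "external"),
                             unit = c("response", "pooled")) {
  kind <- match.arg(kind)
  unit <- match.arg(unit)
  col <- paste0(kind, "_accurate")

  long <- accuracy |>
    dplyr::filter(!is.na(.data[[col]])) |>
    dplyr::mutate(group = ifelse(.data$nutrient %in% MACRO_NUTRIENTS,
                                 "macro", "micro"))

  if (unit == "pooled") {
    x <- as.numeric(long[[col]][long$group == "macro"])
    y <- as.numeric(long[[col]][long$group == "micro"])
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    return(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                n_pairs = c(macro = length(x), micro = length(y)),
                macro_mean = mean(x), micro_mean = mean(y),
                method = "rank-sum on pooled nutrient flags"))
  }

  pairs <- long |>
    dplyr::group_by(.data$response_id, .data$group) |>
    dplyr::summarise(value = mean(.data[[col]]), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "value") |>
    dplyr::filter(!is.na(.data$macro) & !is.na(.data$micro))
  if (nrow(pairs) == 0) stop("no scorable paired responses", call. = FALSE)

  diffs <- pairs$macro - pairs$micro
  n_nonzero <- sum(diffs != 0)
  if (n_nonzero == 0) {
    warning("all macro-micro differences are zero; p = 1", call. = FALSE)
    return(list(statistic = 0, p_value = 1, n_pairs = 0,
                macro_mean = mean(pairs$macro),
                micro_mean = mean(pairs$micro),
                method = "signed-rank (degenerate: all differences zero)"))
  }
  use_exact <- n_nonzero <= 25
  wt <- suppressWarnings(stats::wilcox.test(pairs$macro, pairs$micro,
                                            paired = TRUE,
                                            exact = use_exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_pairs = n_nonzero,
       macro_mean = mean(pairs$macro), micro_mean = mean(pairs$micro),
       method = paste0("paired signed-rank over responses (",
                       if (use_exact) "exact when untied" else
                         "normal approximation", ")"))
}

#' Compare qualitative error burden by cuisine preference
#'
#' Splits per-response consensus error counts by whether the originating
#' prompt carried a cuisine preference and compares the two groups with a
#' two-sided Wilcoxon rank-sum test (tie-corrected normal approximation
#' when ties or large samples preclude the exact null).
#'
#' @param consensus A tibble from [majority_consensus()].
#' @param cohort The cohort tibble.
#' @param meta Response metadata (`response_id, prompt_id`).
#' @return A list: `statistic`, `p_value`, group sizes and mean errors
#'   per response `with_preference` / `without_preference`.
#' @export
cuisine_error_test <- function(consensus, cohort, meta) {
  joined <- dplyr::inner_join(consensus, meta, by = "response_id")
  has_pref <- !is.na(cohort$cuisine_preference[match(joined$prompt_id,
                                                     cohort$id)])
  if (any(is.na(has_pref))) {
    stop("responses reference prompts absent from the cohort",
         call. = FALSE)
  }
  x <- joined$error_count[has_pref]
  y <- joined$error_count[!has_pref]
  if (length(x) == 0 || length(y) == 0) {
    stop("both preference groups must be non-empty", call. = FALSE)
  }
  exact <- length(x) <= 25 && length(y) <= 25 &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n = c(with_preference = length(x), without_preference = length(y)),
       mean_errors = c(with_preference = mean(x),
                       without_preference = mean(y)))
}
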