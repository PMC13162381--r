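#' Read reviewer annotations of qualitative errors
#'
#' Annotation CSVs carry one row per (response, reviewer) with the five
#' 0/1 error-category columns (`hallucination, technical_error,
#' atypical_recommendation, vague_instruction, composite_food_error`) and
#' an optional free-text `note`.
#'
#' @param path CSV path.
#' @return A tibble with logical category columns.
#' @export
read_annotations <- function(path) {
  ann <- readr::read_csv(path, show_col_types = FALSE)
  validate_annotations(ann)
}

validate_annotations <- function(ann) {
  need <- c("response_id", "reviewer_id", QUAL_CATEGORIES)
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols) > 0) {
    stop("annotations lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (cat in QUAL_CATEGORIES) {
    v <- ann[[cat]]
    if (is.numeric(v)) {
      if (any(!v %in% c(0, 1))) {
        stop("column ", cat, " must be 0/1", call. = FALSE)
      }
      ann[[cat]] <- v == 1
    } else if (!is.logical(v)) {
      stop("column ", cat, " must be logical or 0/1", call. = FALSE)
    }
    if (any(is.na(ann[[cat]]))) {
      stop("column ", cat, " has missing flags", call. = FALSE)
    }
  }
  if (!"note" %in% names(ann)) ann$note <- NA_character_
  ann
}

#' Aggregate reviewer annotations by majority rule
#'
#' Each error category is flagged in the consensus when strictly more
#' than half of the reviewers flagged it. With an even reviewer count a
#' tied category resolves to "not flagged" with a warning (three
#' reviewers, the usual design, cannot tie). Every response must carry
#' exactly one annotation from each reviewer.
#'
#' @param annotations A tibble as returned by [read_annotations()] or
#'   [synthesize_annotations()].
#' @param reviewers Character vector of expected reviewer ids; defaults
#'   to all reviewers present.
#' @return A tibble with one row per response: the five consensus flags
#'   and `error_count`, the number of flagged categories (0--5).
#' @export
majority_consensus <- function(annotations, reviewers = NULL) {
  annotations <- validate_annotations(annotations)
  reviewers <- reviewers %||% sort(unique(annotations$reviewer_id))
  n_rev <- length(reviewers)

  bad_rev <- setdiff(unique(annotations$reviewer_id), reviewers)
  if (length(bad_rev) > 0) {
    stop("unknown reviewer(s): ", paste(bad_rev, collapse = ", "),
         call. = FALSE)
  }
  counts <- annotations |>
    dplyr::count(.data$response_id, .data$reviewer_id)
  if (any(counts$n > 1)) {
    stop("duplicate annotation for response(s): ",
         paste(unique(counts$response_id[counts$n > 1]), collapse = ", "),
         call. = FALSE)
  }
  per_resp <- counts |> dplyr::count(.data$response_id)
  if (any(per_resp$n != n_rev)) {
    stop("response(s) missing annotations from some reviewer: ",
         paste(per_resp$response_id[per_resp$n != n_rev], collapse = ", "),
         call. = FALSE)
  }

  votes <- annotations |>
    dplyr::group_by(.data$response_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(QUAL_CATEGORIES), sum),
                     .groups = "drop")
  if (n_rev %% 2 == 0) {
    tied <- vapply(QUAL_CATEGORIES, function(cat) {
      any(votes[[cat]] == n_rev / 2)
    }, logical(1))
    if (any(tied)) {
      warning("tied vote(s) with an even reviewer count resolve to ",
              "'not flagged'", call. = FALSE)
    }
  }
  for (cat in QUAL_CATEGORIES) votes[[cat]] <- votes[[cat]] > n_rev / 2
  votes$error_count <- rowSums(as.matrix(votes[QUAL_CATEGORIES]))
  votes
}

#' Prevalence of qualitative errors by model
#'
#' @param consensus A tibble from [majority_consensus()].
#' @param meta Response metadata (`response_id, model_id`), e.g. from
#'   [responses_meta()].
#' @return A tibble `model_id, category, n_flagged, n_responses, percent`
#'   with integer-rounded percentages.
#' @export
error_prevalence <- function(consensus, meta) {
  if (nrow(consensus) == 0) stop("consensus set is empty", call. = FALSE)
  joined <- dplyr::inner_join(consensus, meta, by = "response_id")
  if (nrow(joined) == 0) {
    stop("no consensus records match the response metadata", call. = FALSE)
  }
  joined |>
    tidyr::pivot_longer(dplyr::all_of(QUAL_CATEGORIES),
                        names_to = "category", values_to = "flagged") |>
    dplyr::group_by(.data$model_id, .data$category) |>
    dplyr::summarise(n_flagged = sum(.data$flagged),
                     n_responses = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(
      percent = round(100 * .data$n_flagged / .data$n_responses),
      category = factor(.data$category, levels = QUAL_CATEGORIES)) |>
    dplyr::arrange(.data$model_id, .data$category) |>
    dplyr::mutate(category = as.character(.data$category))
}

#' Synthesize reviewer annotations for a batch of responses
#'
#' Draws a latent truth for each response and category (probability per
#' the error model, higher for prompts with a cuisine preference), then
#' lets each reviewer independently disagree with the truth with
#' `reviewer_flip_prob`. Stands in for the human annotation step; no text
#' classification of the responses is attempted.
#'
#' @param meta Response metadata (`response_id, prompt_id`), e.g. from
#'   [responses_meta()].
#' @param cohort The cohort tibble (for cuisine preference).
#' @param error_model A [response_error_model()].
#' @param reviewers Character vector of reviewer ids (default three).
#' @param seed Optional integer seed.
#' @return An annotation tibble (see [read_annotations()]).
#' @export
synthesize_annotations <- function(meta, cohort,
                                   error_model = realistic_error_model(),
                                   reviewers = c("R1", "R2", "R3"),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  has_pref <- !is.na(cohort$cuisine_preference[match(meta$prompt_id,
                                                     cohort$id)])
  n <- nrow(meta)
  out <- list()
  latent <- sapply(QUAL_CATEGORIES, function(cat) {
    p <- ifelse(has_pref, error_model$cuisine_error_probs[[cat]],
                error_model$qualitative_error_probs[[cat]])
    rbinom(n, 1, p) == 1
  })
  latent <- matrix(latent, nrow = n,
                   dimnames = list(NULL, QUAL_CATEGORIES))
  for (rev in reviewers) {
    flips <- matrix(rbinom(n * length(QUAL_CATEGORIES), 1,
                           error_model$reviewer_flip_prob) == 1,
                    nrow = n)
    seen <- xor(latent, flips)
    df <- tibble::as_tibble(seen)
    df$response_id <- meta$response_id
    df$reviewer_id <- rev
    out[[rev]] <- df
  }
  dplyr::bind_rows(out) |>
    dplyr::mutate(note = NA_character_) |>
    dplyr::select("response_id", "reviewer_id",
                  dplyr::all_of(QUAL_CATEGORIES), "note")
}
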