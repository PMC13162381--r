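#' Published chatbot concordance percentages (benchmark data)
#'
#' Percent of responses judged concordant per nutrient for four
#' commercial chatbots (ChatGPT, Claude, Gemini, Llama) in a published
#' 2025 evaluation of hemodialysis meal planning, bundled as benchmark
#' data. These numbers characterize the chatbots' behavior at the time of
#' that evaluation; they are inputs for comparison and aggregation, not
#' quantities this package recomputes.
#'
#' @param kind `"internal"` (concordance with prompt goals) or
#'   `"external"` (concordance with reference databases).
#' @return A tibble `model_id, nutrient, percent`.
#' @examples
#' tab <- published_chatbot_accuracy("internal")
#' # mean concordance over the macronutrient cells:
#' mean(tab$percent[tab$nutrient %in% macro_nutrients()])
#' @export
published_chatbot_accuracy <- function(kind = c("internal", "external")) {
  kind <- match.arg(kind)
  cells <- if (kind == "external") {
    list(ChatGPT = c(42, 52, 28, 9, 24, 40, 18),
         Claude = c(38, 34, 24, 8, 12, 10, 16),
         Gemini = c(28, 50, 32, 10, 12, 8, 24),
         Llama = c(12, 28, 26, 36, 6, 20, 8))
  } else {
    list(ChatGPT = c(80, 86, 50, 98, 92, 96, 98),
         Claude = c(30, 56, 38, 98, 92, 100, 100),
         Gemini = c(24, 62, 34, 100, 96, 100, 100),
         Llama = c(70, 70, 28, 98, 70, 76, 100))
  }
  dplyr::bind_rows(lapply(names(cells), function(m) {
    tibble::tibble(model_id = m, nutrient = NUTRIENTS,
                   percent = cells[[m]])
  }))
}

#' Published qualitative error prevalence (benchmark data)
#'
#' Percent of responses carrying each qualitative usability error for the
#' same four chatbots, from the same published evaluation.
#'
#' @return A tibble `model_id, category, percent`.
#' @export
published_chatbot_qualitative <- function() {
  cells <- list(ChatGPT = c(0, 6, 34, 30, 52),
                Claude = c(0, 0, 4, 38, 70),
                Gemini = c(0, 4, 2, 22, 20),
                Llama = c(0, 0, 0, 8, 22))
  dplyr::bind_rows(lapply(names(cells), function(m) {
    tibble::tibble(model_id = m, category = QUAL_CATEGORIES,
                   percent = cells[[m]])
  }))
}
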