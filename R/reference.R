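REFERENCE_SOURCES <- c("USDA", "MW", "AUSNUT")

REFERENCE_COLUMNS <- c("source", "food_id", "name", "calories_kcal",
                       "protein_g", "fiber_g", "calcium_mg", "phosphorus_mg",
                       "potassium_mg", "sodium_mg")

## column in the reference table holding each nutrient, per 100 g
REF_NUTRIENT_COLUMNS <- c(calories = "calories_kcal", protein = "protein_g",
                          fiber = "fiber_g", calcium = "calcium_mg",
                          phosphorus = "phosphorus_mg",
                          potassium = "potassium_mg", sodium = "sodium_mg")

#' Normalize a food name for matching
#'
#' Lowercases, strips parenthetical descriptors, replaces punctuation with
#' spaces and collapses whitespace, so that "White Rice (cooked)" and
#' "white rice, cooked" normalize identically.
#'
#' @param x Character vector of food names.
#' @return Character vector of normalized names.
#' @export
normalize_food_name <- function(x) {
  x <- tolower(x)
  x <- gsub("\\s*\\([^)]*\\)", "", x)
  x <- gsub("[^a-z0-9 ]", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Read one food-composition table from CSV
#'
#' Expects per-100 g columns `source, food_id, name, calories_kcal,
#' protein_g, fiber_g, calcium_mg, phosphorus_mg, potassium_mg, sodium_mg`.
#' Every nutrient value must be present and non-negative; malformed rows
#' are reported with their row number.
#'
#' @param path Path to a CSV file.
#' @return A tibble with the columns above plus `name_normalized`.
#' @export
read_reference_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           source = readr::col_character(),
                           food_id = readr::col_character(),
                           name = readr::col_character(),
                           .default = readr::col_double()))
  missing_cols <- setdiff(REFERENCE_COLUMNS, names(tab))
  if (length(missing_cols) > 0) {
    stop("reference table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_reference_table(tab, path)
}

validate_reference_table <- function(tab, label = "reference table") {
  if (nrow(tab) == 0) stop(label, " is empty", call. = FALSE)
  nut <- as.matrix(tab[REF_NUTRIENT_COLUMNS])
  bad <- which(rowSums(is.na(nut) | nut < 0) > 0 | is.na(tab$source) |
                 is.na(tab$food_id) | is.na(tab$name))
  if (length(bad) > 0) {
    stop(label, ": malformed row(s) at line(s) ",
         paste(head(bad, 5) + 1, collapse = ", "),
         " (missing or negative values)", call. = FALSE)
  }
  bad_src <- setdiff(unique(tab$source), REFERENCE_SOURCES)
  if (length(bad_src) > 0) {
    stop(label, ": unknown source(s) ", paste(bad_src, collapse = ", "),
         call. = FALSE)
  }
  dup <- tab |>
    dplyr::count(.data$source, .data$food_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop(label, ": duplicate food_id within source: ",
         paste(dup$food_id, collapse = ", "), call. = FALSE)
  }
  tab$name_normalized <- normalize_food_name(tab$name)
  tab
}

#' Merge food-composition tables with source priority
#'
#' When the same normalized food name appears in several sources, the
#' record kept follows the priority USDA > MW (McCance--Widdowson) >
#' AUSNUT, regardless of input order. The number of duplicate records
#' dropped is reported as a message.
#'
#' @param tables A list of tibbles from [read_reference_table()] (a single
#'   tibble is accepted).
#' @return The merged tibble.
#' @export
merge_reference_tables <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (length(tables) == 0) stop("no tables to merge", call. = FALSE)
  all_rows <- dplyr::bind_rows(tables)
  if (!"name_normalized" %in% names(all_rows)) {
    all_rows <- validate_reference_table(all_rows)
  }
  merged <- all_rows |>
    dplyr::arrange(match(.data$source, REFERENCE_SOURCES),
                   .data$food_id) |>
    dplyr::distinct(.data$name_normalized, .keep_all = TRUE)
  n_dropped <- nrow(all_rows) - nrow(merged)
  if (n_dropped > 0) {
    message(n_dropped, " duplicate record(s) dropped by source priority")
  }
  merged
}

#' Load and merge food-composition tables from CSV files
#'
#' @param paths Character vector of CSV paths; see
#'   [read_reference_table()] for the schema.
#' @return A merged tibble (see [merge_reference_tables()]).
#' @export
load_reference_table <- function(paths) {
  if (length(paths) == 0) stop("at least one table path required",
                               call. = FALSE)
  merge_reference_tables(lapply(paths, read_reference_table))
}

#' Bundled synthetic food-composition fixture
#'
#' A small synthetic table of about sixty common foods with realistic
#' per-100 g nutrient values, spread over three sources with a few shared
#' names so that merge priority is exercised. It stands in for the
#' proprietary merged USDA / McCance--Widdowson / AUSNUT database; its
#' values are plausible but synthetic and must not be used for actual
#' dietary advice.
#'
#' @param merged If `TRUE` (default) the table is merged with source
#'   priority; if `FALSE` the raw rows (including duplicates) are
#'   returned.
#' @return A reference-table tibble.
#' @export
example_reference_table <- function(merged = TRUE) {
  path <- system.file("extdata", "food_composition_synthetic.csv",
                      package = "renalmeal", mustWork = TRUE)
  tab <- read_reference_table(path)
  if (merged) suppressMessages(merge_reference_tables(tab)) else tab
}

#' Suggest portion-mapping candidates by normalized-name match
#'
#' A convenience helper for building a [PortionMapping] file: exact
#' matching of normalized item names against normalized table names.
#' Matches are suggestions only; the `grams` column is left `NA` for the
#' curator to fill in.
#'
#' @param item_names Character vector of item names as written in
#'   responses.
#' @param table A merged reference table.
#' @return A tibble `item_name, food_id, grams` with `food_id` `NA` where
#'   no exact normalized match exists.
#' @name suggest_mapping
#' @aliases PortionMapping
#' @export
suggest_mapping <- function(item_names, table) {
  idx <- match(normalize_food_name(item_names), table$name_normalized)
  tibble::tibble(item_name = item_names,
                 food_id = table$food_id[idx],
                 grams = NA_real_)
}

validate_mapping <- function(mapping, table) {
  need <- c("item_name", "food_id", "grams")
  missing_cols <- setdiff(need, names(mapping))
  if (length(missing_cols) > 0) {
    stop("mapping lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  known <- is.na(mapping$food_id) | mapping$food_id %in% table$food_id
  if (!all(known)) {
    stop("mapping references unknown food_id: ",
         paste(unique(mapping$food_id[!known]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(mapping$grams) & mapping$grams <= 0)) {
    stop("mapping grams must be positive", call. = FALSE)
  }
  mapping
}

#' Reference daily nutrient totals for one meal-plan response
#'
#' Computes, for each scored nutrient, the daily total implied by the
#' reference table: the sum over mapped items of the per-100 g value
#' scaled by the mapped portion grams. Items with no mapping entry (e.g.
#' composite foods that cannot be decomposed) are excluded from the totals
#' and counted.
#'
#' @param plan A meal-plan record (see [read_responses()]).
#' @param mapping A portion-mapping tibble `item_name, food_id, grams`
#'   (grams per stated portion).
#' @param table A merged reference table.
#' @return A named numeric vector over the seven nutrients, with
#'   attributes `n_items`, `n_unmatched` and `unmatched_items`.
#' @export
reference_totals <- function(plan, mapping, table) {
  mapping <- validate_mapping(mapping, table)
  items <- unlist(lapply(plan$meals, function(m) {
    vapply(m$items, function(it) it$item_name, character(1))
  }))
  totals <- setNames(numeric(length(NUTRIENTS)), NUTRIENTS)
  unmatched <- character(0)
  if (length(items) > 0) {
    idx <- match(normalize_food_name(items),
                 normalize_food_name(mapping$item_name))
    matched <- !is.na(idx) & !is.na(mapping$food_id[idx])
    unmatched <- items[!matched]
    if (any(matched)) {
      rows <- match(mapping$food_id[idx[matched]], table$food_id)
      grams <- mapping$grams[idx[matched]]
      per100 <- as.matrix(table[rows, REF_NUTRIENT_COLUMNS])
      totals <- setNames(colSums(per100 * grams / 100), NUTRIENTS)
    }
  }
  structure(totals, n_items = length(items),
            n_unmatched = length(unmatched),
            unmatched_items = unmatched)
}

#' Reference totals for many responses, with scorability flags
#'
#' @param records A list of meal-plan records.
#' @param mapping,table As in [reference_totals()].
#' @param max_unmatched_frac Responses whose fraction of unmapped items
#'   exceeds this value (default 0.25) are flagged unscorable for external
#'   concordance.
#' @return A long tibble `response_id, nutrient, reference,
#'   unmatched_frac, scorable_external`.
#' @export
reference_totals_all <- function(records, mapping, table,
                                 max_unmatched_frac = 0.25) {
  dplyr::bind_rows(lapply(records, function(rec) {
    tot <- reference_totals(rec, mapping, table)
    frac <- if (attr(tot, "n_items") == 0) 1 else
      attr(tot, "n_unmatched") / attr(tot, "n_items")
    tibble::tibble(response_id = rec$response_id,
                   nutrient = NUTRIENTS,
                   reference = as.numeric(tot),
                   unmatched_frac = frac,
                   scorable_external = frac <= max_unmatched_frac)
  }))
}
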