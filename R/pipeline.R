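#' Configure an end-to-end evaluation run
#'
#' One config and one seed drive the whole pipeline: cohort simulation,
#' prompt rendering, synthetic response generation, concordance scoring,
#' qualitative annotation and consensus, and the two statistical
#' comparisons. The root seed spawns per-stage child seeds so a stage can
#' be rerun independently without perturbing the draws of other stages.
#'
#' @param n Cohort size (number of prompts).
#' @param seed Root seed.
#' @param models Character vector of synthetic model identifiers.
#' @param cohort A [cohort_config()]; its `n` and `seed` are overridden
#'   by this function's `n` and the derived stage seed.
#' @param error_model A [response_error_model()] (or named per-model
#'   list).
#' @param scoring A [scoring_config()].
#' @param reviewers Reviewer ids for synthetic annotation.
#' @param reference_paths Optional CSV paths for the reference table;
#'   defaults to the bundled synthetic fixture.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n = 50, seed = 1,
                            models = paste0("model_", c("A", "B", "C", "D")),
                            cohort = cohort_config(),
                            error_model = realistic_error_model(),
                            scoring = scoring_config(),
                            reviewers = c("R1", "R2", "R3"),
                            reference_paths = NULL) {
  cohort$n <- n
  structure(list(n = n, seed = seed, models = models, cohort = cohort,
                 error_model = error_model, scoring = scoring,
                 reviewers = reviewers, reference_paths = reference_paths),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Accepts the scalar fields of [pipeline_config()] (`n_patients` — named
#' so because a bare `n` is a YAML 1.1 boolean — plus `seed`, `models`,
#' `reviewers`, `reference_paths`) and nested `error_model` and `scoring`
#' blocks whose entries are passed to the respective constructors;
#' anything omitted takes the package default.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw),
                        c("seed", "models", "reviewers",
                          "reference_paths"))]
  if (!is.null(raw$n_patients)) args$n <- raw$n_patients
  if (!is.null(raw$error_model)) {
    em <- raw$error_model
    for (nm in c("bias", "noise_sigma", "missing_prob",
                 "qualitative_error_probs", "cuisine_error_probs")) {
      if (!is.null(em[[nm]])) em[[nm]] <- unlist(em[[nm]])
    }
    args$error_model <- do.call(response_error_model, em)
  }
  if (!is.null(raw$scoring)) {
    args$scoring <- do.call(scoring_config, raw$scoring)
  }
  do.call(pipeline_config, args)
}

#' Run the evaluation pipeline end to end
#'
#' Executes cohort -> prompts -> synthetic responses -> scoring ->
#' qualitative consensus -> statistics, deterministically for a given
#' config and seed. When `out_dir` is given, writes the cohort and its
#' summary, the prompts, the responses (JSON lines) and portion mapping,
#' the concordance table and its external/internal summaries, the
#' deviation summary, the qualitative consensus and prevalence tables,
#' a JSON file with both statistical tests, and a run manifest with
#' record counts at every stage boundary.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return (Invisibly) a list with every intermediate and final artifact
#'   plus `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  started <- Sys.time()

  cohort_cfg <- config$cohort
  cohort_cfg$n <- config$n
  cohort_cfg$seed <- child_seed(config$seed, 1)
  cohort <- simulate_cohort(cohort_cfg)
  summary_tab <- cohort_summary(cohort)
  prompts <- render_prompts(cohort)

  table <- if (is.null(config$reference_paths)) {
    example_reference_table()
  } else {
    load_reference_table(config$reference_paths)
  }

  synth <- synthesize_responses(cohort, table, config$error_model,
                                models = config$models,
                                seed = child_seed(config$seed, 2))
  records <- synth$records
  mapping <- synth$mapping
  meta <- responses_meta(records)

  accuracy <- score_responses(records, cohort, table, mapping,
                              config$scoring)
  external_summary <- accuracy_summary(accuracy, "external")
  internal_summary <- accuracy_summary(accuracy, "internal")
  deviations <- suppressWarnings(deviation_summary(accuracy))

  em0 <- if (inherits(config$error_model, "response_error_model")) {
    config$error_model
  } else {
    config$error_model[[1]]
  }
  annotations <- synthesize_annotations(meta, cohort, em0,
                                        reviewers = config$reviewers,
                                        seed = child_seed(config$seed, 3))
  consensus <- majority_consensus(annotations, config$reviewers)
  prevalence <- error_prevalence(consensus, meta)

  mm_internal <- suppressWarnings(macro_micro_test(accuracy, "internal"))
  mm_external <- suppressWarnings(macro_micro_test(accuracy, "external"))
  cuisine <- tryCatch(cuisine_error_test(consensus, cohort, meta),
                      error = function(e) list(error = conditionMessage(e)))

  manifest <- list(
    seed = config$seed,
    stage_seeds = list(cohort = child_seed(config$seed, 1),
                       responses = child_seed(config$seed, 2),
                       annotations = child_seed(config$seed, 3)),
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("renalmeal")),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    counts = list(
      patients = nrow(cohort),
      prompts = nrow(prompts),
      responses = length(records),
      accuracy_rows = nrow(accuracy),
      accuracy_rows_expected = length(records) * length(NUTRIENTS),
      annotations = nrow(annotations),
      consensus = nrow(consensus)))
  if (manifest$counts$accuracy_rows !=
      manifest$counts$accuracy_rows_expected) {
    stop("stage 'scoring': accuracy rows (",
         manifest$counts$accuracy_rows, ") do not reconcile with ",
         manifest$counts$accuracy_rows_expected, " expected",
         call. = FALSE)
  }

  results <- list(cohort = cohort, cohort_summary = summary_tab,
                  prompts = prompts, reference_table = table,
                  records = records, mapping = mapping,
                  accuracy = accuracy,
                  external_summary = external_summary,
                  internal_summary = internal_summary,
                  deviations = deviations,
                  annotations = annotations, consensus = consensus,
                  prevalence = prevalence,
                  stats = list(macro_micro_internal = mm_internal,
                               macro_micro_external = mm_external,
                               cuisine = cuisine),
                  manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, name) readr::write_csv(x, file.path(out_dir, name))
    w(cohort, "cohort.csv")
    w(summary_tab, "cohort_summary.csv")
    w(prompts, "prompts.csv")
    w(mapping, "mapping.csv")
    w(accuracy, "accuracy.csv")
    w(external_summary, "external_accuracy_summary.csv")
    w(internal_summary, "internal_accuracy_summary.csv")
    w(deviations, "deviation_summary.csv")
    w(annotations, "annotations.csv")
    w(consensus, "qualitative_consensus.csv")
    w(prevalence, "qualitative_prevalence.csv")
    write_responses(records, file.path(out_dir, "responses.jsonl"))
    jsonlite::write_json(results$stats, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(results)
}
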