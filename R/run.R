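#' Assemble a full-run configuration
#'
#' Bundles everything one end-to-end run needs: the cohort generator
#' configuration, the specialist-pathway branch probabilities, the yield
#' scenarios, the two-arm comparisons, and the output directory. Defaults
#' reproduce the pilot's study conditions.
#'
#' @param cohort a [cohort_config()].
#' @param pathway a [pathway_probabilities()].
#' @param scenarios list of [projection_scenario()] objects.
#' @param comparisons named list of comparisons, each a list with elements
#'   `outcome`, `arm1`, `arm2` (see [pilot_comparisons()]).
#' @param output_dir directory the report bundle is written to.
#' @param n_target uptake denominator for the metrics report; defaults to
#'   the cohort's target-population size.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       pathway = pathway_probabilities(),
                       scenarios = pilot_scenarios(),
                       comparisons = pilot_comparisons(),
                       output_dir = tempfile("psascreen-run-"),
                       n_target = NULL) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(pathway, "pathway_probabilities"),
            is.list(scenarios), is.list(comparisons))
  structure(
    list(cohort = cohort, pathway = pathway, scenarios = scenarios,
         comparisons = comparisons, output_dir = output_dir,
         n_target = n_target %||% cohort$n_target_population),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' The file holds flat key-value sections `cohort`, `pathway`, `scenarios`
#' (a list of rows) and `comparisons` (rows with `outcome`, `events1`,
#' `denominator1`, `events2`, `denominator2`); missing sections fall back
#' to the pilot defaults. Dates are ISO-8601 strings.
#'
#' @param path YAML file path.
#' @param output_dir output directory override.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, output_dir = tempfile("psascreen-run-")) {
  raw <- yaml::read_yaml(path)
  cohort <- if (is.null(raw$cohort)) cohort_config() else {
    a <- raw$cohort
    for (d in c("enrollment_start", "data_cutoff")) {
      if (!is.null(a[[d]])) a[[d]] <- as.Date(a[[d]])
    }
    if (!is.null(a$ats_weights)) a$ats_weights <- unlist(a$ats_weights)
    do.call(cohort_config, a)
  }
  pathway <- if (is.null(raw$pathway)) pathway_probabilities() else {
    do.call(pathway_probabilities, raw$pathway)
  }
  scenarios <- if (is.null(raw$scenarios)) pilot_scenarios() else {
    lapply(raw$scenarios, function(s) do.call(projection_scenario, s))
  }
  comparisons <- if (is.null(raw$comparisons)) pilot_comparisons() else {
    lapply(raw$comparisons, function(cc) {
      list(outcome = cc$outcome,
           arm1 = arm_counts(cc$events1, cc$denominator1),
           arm2 = arm_counts(cc$events2, cc$denominator2))
    })
  }
  run_config(cohort = cohort, pathway = pathway, scenarios = scenarios,
             comparisons = comparisons, output_dir = output_dir,
             n_target = raw$n_target)
}

#' Run the whole screening model end to end
#'
#' Generates (or accepts) a cohort, triages it, runs the specialist
#' pathway, and computes the metrics report, risk-stratification table,
#' pathway summary, yield projections and two-arm comparisons. All tables
#' are written to `config$output_dir` as comma-separated text together
#' with a YAML run manifest (seed, package version, configuration echo).
#' The run is a pure function of (configuration, seed): identical inputs
#' give identical bundles.
#'
#' @param config a [run_config()].
#' @param records optional pre-built participant table (e.g.
#'   [pilot_cohort()]); if `NULL` a cohort is generated from
#'   `config$cohort`.
#' @return Invisibly, a list with `records`, `metrics`, `category_table`,
#'   `pathway` (the [run_pathway()] result), `projections`, `comparisons`
#'   and `output_dir`.
#' @export
#' @examples
#' cfg <- run_config(cohort = cohort_config(n_target_population = 2000,
#'                                          seed = 42))
#' bundle <- full_run(cfg)
#' bundle$metrics
full_run <- function(config, records = NULL) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  }

  if (is.null(records)) records <- generate_cohort(config$cohort)
  triaged <- triage_table(records)
  path <- run_pathway(triaged, config$pathway,
                      seed = config$cohort$seed + 1L)
  metrics <- compute_metrics(path$records,
                             n_target = max(config$n_target,
                                            sum(triaged$answered_questionnaire,
                                                na.rm = TRUE)))
  cat_tab <- category_table(path$records)
  projections <- scenario_grid(config$scenarios)
  comparisons <- dplyr::bind_rows(lapply(config$comparisons, function(cc) {
    dplyr::bind_cols(tibble::tibble(outcome = cc$outcome),
                     compare_proportions(cc$arm1, cc$arm2))
  }))

  write_cohort(path$records, file.path(out_dir, "participants.csv"))
  write_event_log(path$events, file.path(out_dir, "pathway_events.csv"))
  write.csv(cat_tab, file.path(out_dir, "category_table.csv"),
            row.names = FALSE)
  write.csv(projections, file.path(out_dir, "projections.csv"),
            row.names = FALSE)
  write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
            row.names = FALSE)
  write.csv(metrics$per_ats, file.path(out_dir, "per_ats.csv"),
            row.names = FALSE)
  metrics_flat <- metrics[!names(metrics) %in% c("category_counts",
                                                 "per_ats", "data_cutoff")]
  write.csv(tibble::tibble(metric = names(metrics_flat),
                           value = unlist(metrics_flat)),
            file.path(out_dir, "metrics.csv"), row.names = FALSE)
  summary_flat <- config_summary(config)
  summary_flat$pathway_counts <-
    lapply(path$summary[names(path$summary) != "terminal_counts"], unclass)
  summary_flat$terminal_counts <- as.list(path$summary$terminal_counts)
  yaml::write_yaml(summary_flat, file.path(out_dir, "manifest.yaml"))

  invisible(list(records = path$records, metrics = metrics,
                 category_table = cat_tab, pathway = path,
                 projections = projections, comparisons = comparisons,
                 output_dir = out_dir))
}

config_summary <- function(config) {
  list(
    package = "psascreen",
    version = as.character(utils::packageVersion("psascreen")),
    seed = config$cohort$seed,
    cohort = lapply(config$cohort, function(x) {
      if (inherits(x, "Date")) format(x) else unclass(x)
    }),
    n_target = config$n_target,
    pathway = unclass(config$pathway),
    scenarios = lapply(config$scenarios, function(s) {
      s <- unclass(s)
      s[!vapply(s, is.null, logical(1))]
    })
  )
}
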