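#' Build a run configuration
#'
#' Bundles everything an end-to-end classification run needs. The
#' expected count is a user input taken from external baseline knowledge
#' (the average mortality of typical summer weeks); the framework does
#' not estimate it.
#'
#' @param case_csv,control_csv Paths to the two pool CSV files.
#' @param expected_count Baseline expected deaths (default 297).
#' @param control_ratio Controls per case in each repetition (default 4).
#' @param n_reps Repetitions per trial (study scale 10,000; the default
#'   here is a reduced demonstration scale).
#' @param n_trials Trials per combination (study scale 100).
#' @param combinations Character vector of combination labels from
#'   [standard_combinations()].
#' @param master_seed Integer master seed.
#' @param output_dir Directory for result files.
#' @param event_dates Optional `Date` vector; when `NULL` the event
#'   window is the closed span of case death dates.
#' @return Object of class `run_config`.
#' @export
run_config <- function(case_csv, control_csv, expected_count = 297L,
                       control_ratio = 4L, n_reps = 200L, n_trials = 10L,
                       combinations = names(standard_combinations()),
                       master_seed = 1L, output_dir = "heatexcess_results",
                       event_dates = NULL) {
  known <- names(standard_combinations())
  bad <- setdiff(combinations, known)
  if (length(bad) > 0L)
    stop("unknown combination label(s): ", paste(bad, collapse = ", "))
  structure(list(case_csv = case_csv, control_csv = control_csv,
                 expected_count = as.integer(expected_count),
                 control_ratio = as.integer(control_ratio),
                 n_reps = as.integer(n_reps), n_trials = as.integer(n_trials),
                 combinations = combinations,
                 master_seed = as.integer(master_seed),
                 output_dir = output_dir, event_dates = event_dates),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(run_config)), "")
  unknown <- setdiff(names(y), allowed)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(y$event_dates)) y$event_dates <- as.Date(y$event_dates)
  do.call(run_config, y)
}

#' Read scenario parameters from YAML
#'
#' The file may name a `preset` (`"strong"` or `"null"`) and/or override
#' any [scenario_params()] field; `control_marginals` and `excess_shift`
#' are nested maps with the same field names as in R.
#'
#' @param path YAML scenario file.
#' @return `scenario_params` object.
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  preset <- y$preset %||% "null"
  y$preset <- NULL
  if (!preset %in% c("strong", "null"))
    stop("unknown scenario preset: ", preset)
  base <- formals(scenario_params)
  unknown <- setdiff(names(y), names(base))
  if (length(unknown) > 0L)
    stop("unknown scenario key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(y$event_dates)) y$event_dates <- as.Date(y$event_dates)
  if (!is.null(y$control_dates)) y$control_dates <- as.Date(y$control_dates)
  if (!is.null(y$control_marginals)) {
    m <- utils::modifyList(default_control_marginals(), y$control_marginals)
    m$location <- unlist(m$location); m$deprivation <- unlist(m$deprivation)
    m$density <- unlist(m$density)
    y$control_marginals <- m
  }
  if (!is.null(y$excess_shift)) {
    s <- utils::modifyList(zero_shift(), y$excess_shift)
    s$location <- unlist(s$location); s$deprivation <- unlist(s$deprivation)
    s$density <- unlist(s$density)
    y$excess_shift <- s
  }
  ctor <- if (preset == "strong") scenario_strong else scenario_null
  keep <- intersect(names(y), names(formals(ctor)))
  extra <- setdiff(names(y), keep)
  do.call(ctor, c(y[keep], y[extra]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate scenario pools from a config (CLI: `simulate`)
#'
#' @param scenario A `scenario_params` object or path to a scenario YAML.
#' @param out_dir Output directory.
#' @return Output directory, invisibly.
#' @export
cmd_simulate <- function(scenario, out_dir) {
  params <- if (inherits(scenario, "scenario_params")) scenario
            else read_scenario_config(scenario)
  sim <- simulate_cohort(params)
  write_scenario(sim, out_dir)
  message("wrote ", nrow(sim$cohort$cases), " cases / ",
          nrow(sim$cohort$controls), " controls to ", out_dir)
  invisible(out_dir)
}

# Load a cohort from a run config.
.load_cohort <- function(config) {
  cases <- read_pool(config$case_csv, "case")
  controls <- read_pool(config$control_csv, "control")
  ev <- config$event_dates %||%
    seq(min(cases$death_date), max(cases$death_date), by = "day")
  cohort(cases, controls, ev,
         provenance = paste("files:", config$case_csv, config$control_csv))
}

#' Run the classification for each configured combination (CLI: `run`)
#'
#' Runs [run_combination()] for every requested combination (each on a
#' seed derived from the master seed), writing one per-case CSV per
#' combination, a stability summary CSV, and a JSON run manifest that
#' suffices to reproduce every output.
#'
#' @param config A [run_config()] object or path to a YAML config.
#' @return Named list of `combination_result`s, invisibly.
#' @export
cmd_run <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  ch <- .load_cohort(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  specs <- standard_combinations()[config$combinations]
  set.seed(config$master_seed)
  combo_seeds <- sample.int(2147483646L, length(specs))
  results <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    message("running ", sp$label, " (", config$n_trials, " trials x ",
            config$n_reps, " reps)")
    res <- run_combination(ch, sp, config$n_trials, config$n_reps,
                           config$expected_count, config$control_ratio,
                           seed = combo_seeds[i])
    utils::write.csv(res$per_case,
                     file.path(config$output_dir,
                               paste0("per_case_", sp$label, ".csv")),
                     row.names = FALSE, quote = FALSE)
    results[[sp$label]] <- res
  }
  stab <- stability_summary(results)
  utils::write.csv(stab, file.path(config$output_dir, "stability.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- unclass(config)
  manifest$event_dates <- format(ch$event_dates)
  manifest$combination_seeds <- combo_seeds
  manifest$version <- as.character(utils::packageVersion("heatexcess"))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

#' Post-classification assessment of run outputs (CLI: `assess`)
#'
#' Reads the per-case label CSVs written by [cmd_run()] and produces the
#' assessment outputs: per-combination comparisons of the probable excess
#' and probable expected groups against controls, the pairwise overlap
#' matrix and all-combination consensus, per-combination daily death
#' distributions, and (when ground truth is available) recovery metrics.
#'
#' @param results_dir Directory written by [cmd_run()].
#' @param config The [run_config()] used for the run (or its YAML path).
#' @param truth_csv Optional path to a `truth.csv` from [cmd_simulate()];
#'   when absent, recovery metrics are skipped with a note.
#' @param out_dir Output directory (default `results_dir`).
#' @return List of assessment tables, invisibly.
#' @export
cmd_assess <- function(results_dir, config, truth_csv = NULL,
                       out_dir = results_dir) {
  if (is.character(config)) config <- read_run_config(config)
  ch <- .load_cohort(config)
  files <- list.files(results_dir, "^per_case_.*\\.csv$", full.names = TRUE)
  if (length(files) == 0L) stop("no per_case_*.csv files in ", results_dir)
  labels <- sub("^per_case_(.*)\\.csv$", "\\1", basename(files))
  per_case <- stats::setNames(lapply(files, utils::read.csv,
                                     stringsAsFactors = FALSE), labels)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  excess_sets <- lapply(per_case, function(df)
    df$record_id[df$final_label == "probable_excess"])
  comp_rows <- daily_rows <- list()
  for (lab in labels) {
    for (grp in c("probable_excess", "probable_expected")) {
      ids <- per_case[[lab]]$record_id[per_case[[lab]]$final_label == grp]
      gdf <- ch$cases[ch$cases$record_id %in% ids, , drop = FALSE]
      cmp <- compare_to_controls(gdf, ch$controls)
      cmp$combination <- lab; cmp$group <- grp
      comp_rows[[paste(lab, grp)]] <- cmp
    }
    gdf <- ch$cases[ch$cases$record_id %in% excess_sets[[lab]], , drop = FALSE]
    dd <- daily_distribution(gdf, ch)
    dd$combination <- lab
    daily_rows[[lab]] <- dd
  }
  comparisons <- do.call(rbind, comp_rows)
  daily <- do.call(rbind, daily_rows)
  overlap <- overlap_percent(excess_sets)
  out <- list(comparisons = comparisons, overlap = overlap, daily = daily)
  if (length(excess_sets) >= 2L) out$consensus <- consensus_set(excess_sets)

  utils::write.csv(comparisons, file.path(out_dir, "group_comparisons.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(overlap),
                   file.path(out_dir, "overlap_matrix.csv"), quote = FALSE)
  utils::write.csv(daily, file.path(out_dir, "daily_distribution.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(truth_csv)) {
    truth <- utils::read.csv(truth_csv, stringsAsFactors = FALSE)
    recov <- lapply(per_case, recovery_metrics, truth = truth)
    jsonlite::write_json(recov, file.path(out_dir, "recovery_metrics.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    out$recovery <- recov
  } else {
    message("no truth CSV supplied; recovery metrics skipped")
  }
  invisible(out)
}
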