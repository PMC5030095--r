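# End-to-end pipeline: simulate -> process -> segment -> analyze ->
# classify -> report, seeded from one root seed, writing delimited tables.

#' Default pipeline configuration
#'
#' Nested list describing a small demonstration run: a simulated two-animal
#' population with a mix of archetypes, analyzed with the standard
#' parameters. Any element can be overridden via `...` (top level) or by
#' editing the returned list; [read_pipeline_config()] loads the same
#' structure from JSON.
#'
#' @param ... Top-level overrides (`simulate`, `analysis`).
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(...) {
  cfg <- list(
    simulate = list(
      enabled = TRUE,
      n_trials_dark = 4L, n_trials_stim = 6L,
      animals = list(
        list(animal_id = "m1", cell_type = "VIP", layer = "L2/3",
             archetypes = c("VIP_LIKE", "VIP_LIKE", "SST_LIKE", "NULL")),
        list(animal_id = "m2", cell_type = "VIP", layer = "L2/3",
             archetypes = c("VIP_LIKE", "SST_LIKE", "SST_LIKE", "NULL")))),
    analysis = list(n_boot = 500L, R = 0.35, ci_level = 0.95,
                    lmi_thresh = 0.2, delta_band = 0.2, min_state_s = 5,
                    min_samples = 5L, var_pct = 95,
                    ci_requires_both = FALSE, demix = FALSE))
  merge_config(cfg, list(...))
}

# Recursive config merge; unnamed lists (e.g. `animals`) are replaced
# wholesale because they carry no names to merge by.
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration from a JSON file
#'
#' @param path Path to a JSON file with the structure of
#'   [default_pipeline_config()].
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  merge_config(default_pipeline_config(), cfg)
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Chains simulation (optional), dFF0 processing, behavioral segmentation,
#' modulation statistics, context classification, and the population report.
#' All stages are seeded from `seed`; the same config and seed produce
#' byte-identical output tables. A provenance JSON (config, seed, package
#' version) is written alongside.
#'
#' @param config Configuration list ([default_pipeline_config()]) or path to
#'   a JSON config file.
#' @param seed Integer root seed.
#' @param out_dir Output directory (created if missing).
#' @param input Optional list with `traces`, `schedule`, `speed`, `meta`
#'   (and optionally `neuropil`) when `config$simulate$enabled` is `FALSE`.
#' @return Invisibly, a list with `results`, `classes`, `summaries`,
#'   `tests`, `labels`, and the output paths.
#' @export
run_pipeline <- function(config = default_pipeline_config(), seed = 1L,
                         out_dir = tempfile("locomod_run_"), input = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (isTRUE(config$simulate$enabled)) {
    sims <- list(); metas <- list()
    for (ai in seq_along(config$simulate$animals)) {
      an <- config$simulate$animals[[ai]]
      gts <- lapply(seq_along(an$archetypes), function(k) {
        ground_truth(an$archetypes[[k]],
                     neuron_id = sprintf("%s_n%02d", an$animal_id, k))
      })
      sims[[ai]] <- simulate_population(
        gts, n_trials_dark = config$simulate$n_trials_dark,
        n_trials_stim = config$simulate$n_trials_stim,
        animal_id = an$animal_id, cell_type = an$cell_type,
        layer = an$layer, seed = derive_seed(seed, 7000L + ai))
      metas[[ai]] <- sims[[ai]]$meta
    }
    gt_json <- unlist(lapply(sims, function(s) {
      lapply(s$ground_truth, function(g) unclass(g))
    }), recursive = FALSE)
    names(gt_json) <- vapply(gt_json, function(g) as.character(g$neuron_id),
                             "")
    jsonlite::write_json(gt_json, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    if (is.null(input)) {
      stop("simulate disabled and no `input` supplied: need traces, ",
           "schedule, speed, meta", call. = FALSE)
    }
    for (nm in c("traces", "schedule", "speed", "meta")) {
      if (is.null(input[[nm]])) {
        stop(sprintf("missing input element `%s`", nm), call. = FALSE)
      }
    }
    sims <- list(input)
    metas <- list(input$meta)
  }

  acfg <- do.call(analysis_config, config$analysis)
  all_results <- list(); all_classes <- list()
  for (ai in seq_along(sims)) {
    s <- sims[[ai]]
    ana <- analyze_population(s$traces, s$schedule, s$speed, metas[[ai]],
                              cfg = acfg, neuropil = s$neuropil,
                              seed = derive_seed(seed, 8000L + ai))
    all_results[[ai]] <- ana$results
    all_classes[[ai]] <- ana$classes
    if (ai == 1L) {
      # behavior tables for the first animal (one speed trace per animal)
      labels <- ana$labels
      write_tsv(data.frame(frame = seq_len(nrow(s$speed)),
                           time_s = s$speed$time_s,
                           speed_cm_s = s$speed$speed_cm_s,
                           state = as.character(labels)),
                file.path(out_dir, "behavior_labels.tsv"))
      ep <- enumerate_epochs(labels)
      fz <- attr(s$schedule, "frame_hz")
      write_tsv(data.frame(state = ep$state,
                           start_s = (ep$start_frame - 1) / fz,
                           end_s = ep$end_frame / fz),
                file.path(out_dir, "behavior_epochs.tsv"))
      write_tsv(as.data.frame(s$schedule),
                file.path(out_dir, "stimulus_schedule.tsv"))
    }
  }
  results <- do.call(rbind, all_results)
  classes <- do.call(rbind, all_classes)
  summaries <- aggregate_per_animal(results)
  tests <- suppressWarnings(run_population_tests(summaries))

  write_tsv(results, file.path(out_dir, "lmi_results.tsv"))
  if (!is.null(classes)) {
    write_tsv(classes, file.path(out_dir, "context_classes.tsv"))
  }
  write_tsv(summaries, file.path(out_dir, "population_summary.tsv"))
  write_tsv(tests, file.path(out_dir, "population_tests.tsv"))
  jsonlite::write_json(
    list(seed = seed,
         package_version = as.character(utils::packageVersion("locomod")),
         config = config),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  invisible(list(results = results, classes = classes, summaries = summaries,
                 tests = tests, out_dir = out_dir,
                 files = list.files(out_dir)))
}
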