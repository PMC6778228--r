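#' Write / read the canonical on-disk schema
#'
#' A population is stored as plain text: `trials.csv` (cell, trial,
#' condition labels, event times, outcome), `spikes.csv` (cell_id, trial_id,
#' t_ms relative to stimulus onset), `waveforms.csv` (cell_id, sample_index,
#' amplitude, sampling_khz) and `ground_truth.json` (archetype labels and
#' drug identity). Times are ms with stimulus onset 0; round-tripping
#' preserves values to the 1e-6 ms written precision.
#'
#' @param population a `cell_population`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trials <- dplyr::bind_rows(lapply(population$cells, function(cell) {
    cbind(cell_id = cell$cell_id, cell$trials)
  }))
  spikes <- dplyr::bind_rows(lapply(population$cells, function(cell) {
    idx <- rep(seq_along(cell$spikes), lengths(cell$spikes))
    tibble::tibble(
      cell_id = cell$cell_id,
      trial_id = cell$trials$trial_id[idx],
      t_ms = round(unlist(cell$spikes) %||% numeric(0), 6)
    )
  }))
  waveforms <- dplyr::bind_rows(lapply(population$cells, function(cell) {
    tibble::tibble(
      cell_id = cell$cell_id,
      sample_index = seq_along(cell$waveform$amplitude),
      amplitude = signif(cell$waveform$amplitude, 8),
      sampling_khz = cell$waveform$sampling_khz
    )
  }))
  utils::write.csv(trials, file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(waveforms, file.path(dir, "waveforms.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(
      drug_name = population$drug_name,
      ground_truth = population$ground_truth
    ),
    file.path(dir, "ground_truth.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_population
#' @export
read_population <- function(dir) {
  trials <- utils::read.csv(file.path(dir, "trials.csv"))
  spikes <- utils::read.csv(file.path(dir, "spikes.csv"))
  waveforms <- utils::read.csv(file.path(dir, "waveforms.csv"))
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path, simplifyVector = TRUE) else NULL
  cells <- list()
  for (id in unique(trials$cell_id)) {
    tr <- tibble::as_tibble(trials[trials$cell_id == id, -1])
    sp <- spikes[spikes$cell_id == id, ]
    wf <- waveforms[waveforms$cell_id == id, ]
    spk <- lapply(tr$trial_id, function(t) sp$t_ms[sp$trial_id == t])
    arch <- if (!is.null(gt)) {
      gt$ground_truth$archetype[gt$ground_truth$cell_id == id]
    } else NA_character_
    cells[[id]] <- structure(
      list(
        cell_id = id,
        archetype = if (length(arch)) arch else NA_character_,
        drug_name = tr$drug_name[1],
        waveform = structure(
          list(amplitude = wf$amplitude[order(wf$sample_index)],
               sampling_khz = wf$sampling_khz[1]),
          class = "cholattn_waveform"
        ),
        trials = tr,
        spikes = spk
      ),
      class = "cell_recording"
    )
  }
  structure(
    list(
      cells = cells,
      ground_truth = if (!is.null(gt)) tibble::as_tibble(gt$ground_truth) else
        tibble::tibble(cell_id = names(cells), archetype = NA_character_),
      drug_name = if (!is.null(gt)) gt$drug_name else cells[[1]]$drug_name
    ),
    class = "cell_population"
  )
}

#' Pipeline run configuration
#'
#' Bundles every tunable of a full run: the simulation (or input directory),
#' the analysis windows and thresholds, and the master seed from which every
#' stage seed is derived.
#'
#' @param drugs drug conditions to simulate (subset of ACh/Scop/Mec).
#' @param cells_per_archetype cells per archetype per drug condition.
#' @param design a [task_design()].
#' @param input_dir optional directory with the canonical schema instead of
#'   simulation (one population; overrides `drugs`).
#' @param master_seed integer master seed.
#' @param alpha screen significance level.
#' @param min_trials trial floor for negative-binomial fits.
#' @param k_range cluster-count sweep range.
#' @param screen_threshold explained-variance threshold for feature
#'   screening.
#' @param dip_n_boot bootstrap draws for dip calibration.
#' @param behavior_hit_p,behavior_fa_p,behavior_rt_mean_ms behavioral
#'   generator settings.
#' @param out_dir optional output directory for the result tables.
#' @return a `run_config` list.
#' @export
run_config <- function(drugs = c("ACh", "Scop", "Mec"),
                       cells_per_archetype = 10,
                       design = task_design(),
                       input_dir = NULL,
                       master_seed = 1,
                       alpha = 0.05,
                       min_trials = 5,
                       k_range = 2:12,
                       screen_threshold = 0.90,
                       dip_n_boot = 2000,
                       behavior_hit_p = 0.997,
                       behavior_fa_p = 0.041,
                       behavior_rt_mean_ms = 400,
                       out_dir = NULL) {
  stopifnot(all(drugs %in% c("ACh", "Scop", "Mec")))
  structure(
    list(
      drugs = drugs, cells_per_archetype = cells_per_archetype,
      design = design, input_dir = input_dir, master_seed = master_seed,
      alpha = alpha, min_trials = min_trials, k_range = k_range,
      screen_threshold = screen_threshold, dip_n_boot = dip_n_boot,
      behavior_hit_p = behavior_hit_p, behavior_fa_p = behavior_fa_p,
      behavior_rt_mean_ms = behavior_rt_mean_ms, out_dir = out_dir
    ),
    class = "run_config"
  )
}

# Stable FNV-1a style hash of a configuration for the run manifest.
config_hash <- function(config) {
  raw <- serialize(config[setdiff(names(config), "out_dir")], NULL,
                   version = 2)
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619 %% 2^31
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) the cell populations and behavioral sessions, then
#' runs every analysis stage: per-cell metrics, ANOVA screening, attentional
#' AUROC / Cohen's d per drug state, negative-binomial gain variance,
#' modulation indices, feature screening + mixture clustering with dip
#' tests (on the pooled cells of all drug conditions), and the behavioral
#' summary. When `out_dir` is set, all tables are written as CSV/JSON along
#' with a manifest (config hash, seed, package version); re-running with
#' the same config reproduces identical outputs.
#'
#' @param config a [run_config()].
#' @return a `pipeline_report` list with all stage outputs.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$master_seed
  if (!is.null(config$input_dir)) {
    populations <- list(loaded = read_population(config$input_dir))
    names(populations) <- populations[[1]]$drug_name
  } else {
    populations <- lapply(config$drugs, function(dr) {
      simulate_population(
        archetype_panel(dr), config$cells_per_archetype, config$design,
        seed = derive_seed(seed, paste0("pop/", dr)), drug_name = dr
      )
    })
    names(populations) <- config$drugs
  }

  metrics <- dplyr::bind_rows(lapply(populations, population_metrics))
  attention <- dplyr::bind_rows(lapply(populations, population_attention_stats,
                                       alpha = config$alpha))
  gv <- dplyr::bind_rows(lapply(populations, population_gain_variance,
                                min_trials = config$min_trials))
  mis <- dplyr::bind_rows(lapply(populations, population_modulation_indices,
                                 min_trials = config$min_trials))

  fm <- build_feature_matrix(metrics)
  screened <- screen_parameters(fm, threshold = config$screen_threshold)
  clustering <- NULL
  if (nrow(fm$z) >= max(config$k_range) * 3) {
    sweep <- fit_mixture_sweep(fm$z[, screened$selected, drop = FALSE],
                               k_range = config$k_range,
                               seed = derive_seed(seed, "mixture"))
    sel <- select_k(sweep, cell_class = fm$cell_class)
    summary <- summarize_clusters(sel$assignments, metrics,
                                  dip_n_boot = config$dip_n_boot,
                                  seed = derive_seed(seed, "dip"))
    clustering <- list(sweep = sweep$table, selection = sel,
                       summary = summary)
  }

  behavior <- dplyr::bind_rows(lapply(names(populations), function(dr) {
    simulate_behavior(
      config$design,
      hit_p = config$behavior_hit_p, false_alarm_p = config$behavior_fa_p,
      rt_mean_ms = config$behavior_rt_mean_ms,
      rt_drug_rf_scale = if (dr == "Scop") 1.03 else 1,
      session_id = paste0("session_", dr),
      seed = derive_seed(seed, paste0("behavior/", dr))
    )
  }))
  behavior_sum <- behavior_summary(behavior)

  report <- structure(
    list(
      config = config,
      manifest = list(
        config_hash = config_hash(config),
        master_seed = seed,
        package_version = as.character(utils::packageVersion("cholattn")),
        n_cells = nrow(metrics)
      ),
      populations = populations,
      metrics = metrics,
      attention = attention,
      gain_variance = gv,
      modulation_indices = mis,
      feature_screen = screened,
      clustering = clustering,
      behavior = behavior,
      behavior_summary = behavior_sum
    ),
    class = "pipeline_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$metrics, file.path(dir, "cell_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$attention, file.path(dir, "attention_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(report$gain_variance, file.path(dir, "gain_variance.csv"),
                   row.names = FALSE)
  utils::write.csv(report$modulation_indices,
                   file.path(dir, "modulation_indices.csv"), row.names = FALSE)
  if (!is.null(report$clustering)) {
    utils::write.csv(report$clustering$sweep, file.path(dir, "cluster_sweep.csv"),
                     row.names = FALSE)
    utils::write.csv(
      tibble::tibble(cell_id = names(report$clustering$selection$assignments),
                     cluster = report$clustering$selection$assignments,
                     label = report$clustering$summary$labels),
      file.path(dir, "cluster_assignments.csv"), row.names = FALSE
    )
    jsonlite::write_json(report$clustering$summary$composition,
                         file.path(dir, "cluster_report.json"),
                         dataframe = "columns", auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(report$behavior, file.path(dir, "behavior_trials.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    c(report$manifest,
      list(hit_rate = report$behavior_summary$hit_rate,
           cr_rate = report$behavior_summary$cr_rate,
           d_prime = report$behavior_summary$d_prime)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf(
    "<pipeline_report> %d cells, %d drug condition(s)%s; behavior: hit %.3f, d-prime %.2f\n",
    nrow(x$metrics), length(x$populations),
    if (!is.null(x$clustering)) sprintf(", k = %d clusters", x$clustering$selection$k) else "",
    x$behavior_summary$hit_rate, x$behavior_summary$d_prime
  ))
  invisible(x)
}
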