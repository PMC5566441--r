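#' Read and validate a run configuration file
#'
#' YAML with keys: `amplitude_file`, `layout_file`, `chains_file` (paths,
#' resolved relative to the config file), `droplet_volume`, `ci_level`,
#' `reference_target` (optional, enables copies/genome and
#' transcripts/genome), `qc` (`dynamic_range, droplet_floor, ntc_ceiling,
#' subsampling_cap`), `thresholds` (`mode: auto` and optional `manual:`
#' target-value map), and `seed`.
#'
#' @param path path to a YAML run configuration.
#' @return a validated named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("amplitude_file", "layout_file", "chains_file")) {
    if (is.null(cfg[[key]])) abort(paste0("Config is missing `", key, "`."))
    if (!grepl("^/", cfg[[key]])) cfg[[key]] <- file.path(base, cfg[[key]])
  }
  cfg$droplet_volume <- cfg$droplet_volume %||% 0.85
  cfg$ci_level <- cfg$ci_level %||% 0.95
  if (cfg$ci_level <= 0 || cfg$ci_level >= 1) abort("`ci_level` must be in (0, 1).")
  qc <- cfg$qc %||% list()
  cfg$qc <- qc_defaults(
    dynamic_range = qc$dynamic_range %||% 1e5,
    droplet_floor = qc$droplet_floor %||% 1e4,
    ntc_ceiling = qc$ntc_ceiling %||% 5,
    subsampling_cap = qc$subsampling_cap %||% 0.25)
  if (any(unlist(cfg$qc) <= 0)) abort("All QC thresholds must be positive.")
  cfg$seed <- cfg$seed %||% 1L
  structure(cfg, class = c("run_config", "list"))
}

log_stage <- function(...) message("[selfiedpcr] ", sprintf(...))

#' Run the full Selfie-dPCR analysis pipeline
#'
#' config -> read -> classify -> quantify -> metrics -> report. Writes
#' `counts.csv`, `concentrations.csv`, `metrics.csv` and `manifest.json`
#' into `output_dir` and returns the tables invisibly. The metrics table is
#' long format (`sample,target,metric,estimate,ci_low,ci_high,n,flags`)
#' with one row per replicate-level estimate and one `*_mean` row per
#' (sample, target) carrying the replicate mean with SEM bounds.
#'
#' @param config a [read_run_config()] object, a path to one, or an
#'   equivalent named list.
#' @param output_dir output directory (created if needed).
#' @return invisibly, a list with `counts`, `concentrations`, `metrics`,
#'   and `manifest`.
#' @export
selfie_run <- function(config, output_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  log_stage("reading layout: %s", config$layout_file)
  layout <- read_plate_layout(config$layout_file)
  chains <- read_dilution_chains(config$chains_file)
  log_stage("reading amplitudes: %s", config$amplitude_file)
  wells <- read_amplitude_table(config$amplitude_file, layout)

  log_stage("classifying %d wells", nrow(wells))
  manual <- unlist(config$thresholds$manual) %||% NULL
  counts <- classify_wells(wells, manual = manual)
  write_classified_counts(counts, file.path(output_dir, "counts.csv"))

  log_stage("quantifying")
  quant <- quantify_wells(counts, chains,
                          droplet_volume = config$droplet_volume,
                          level = config$ci_level) |>
    qc_flags(qc = config$qc)
  write_concentrations(quant, file.path(output_dir, "concentrations.csv"))

  log_stage("computing metrics")
  est <- quant |> filter(.data$rt_condition != "NTC")
  tpg <- transcripts_per_gene(est, level = config$ci_level)
  metrics <- tpg |>
    transmute(sample = .data$sample_id, target = .data$target,
              metric = "transcripts_per_gene",
              replicate = .data$replicate,
              estimate = .data$transcripts_per_gene,
              ci_low = .data$ci_low, ci_high = .data$ci_high,
              n = 1L, flags = .data$flags)

  ref <- config$reference_target
  if (!is.null(ref) && ref %in% est$target) {
    cpg <- copies_per_genome(est, ref, level = config$ci_level)
    metrics <- bind_rows(metrics, cpg |>
      transmute(sample = .data$sample_id, target = .data$target,
                metric = "copies_per_genome", replicate = .data$replicate,
                estimate = .data$copies_per_genome,
                ci_low = .data$ci_low, ci_high = .data$ci_high,
                n = 1L, flags = ""))
    tpgen <- tpg |>
      inner_join(cpg, by = c("sample_id", "target", "replicate"),
                 suffix = c("_t", "_c")) |>
      mutate(estimate = transcripts_per_genome(.data$transcripts_per_gene,
                                               .data$copies_per_genome),
             se_prod = sqrt(.data$transcripts_per_gene^2 * .data$se_c^2 +
                              .data$copies_per_genome^2 * .data$se_t^2),
             zc = qnorm(1 - (1 - config$ci_level) / 2))
    metrics <- bind_rows(metrics, tpgen |>
      transmute(sample = .data$sample_id, target = .data$target,
                metric = "transcripts_per_genome", replicate = .data$replicate,
                estimate = .data$estimate,
                ci_low = .data$estimate - .data$zc * .data$se_prod,
                ci_high = .data$estimate + .data$zc * .data$se_prod,
                n = 1L, flags = ""))
  }

  summary_rows <- metrics |>
    group_by(.data$sample, .data$target, .data$metric) |>
    group_modify(function(g, key) {
      agg <- aggregate_replicates(g$estimate)
      tibble(replicate = NA_integer_, estimate = agg$mean,
             ci_low = agg$mean - agg$sem, ci_high = agg$mean + agg$sem,
             n = agg$n,
             flags = paste(unique(g$flags[g$flags != ""]), collapse = ";"))
    }) |>
    ungroup() |>
    mutate(metric = paste0(.data$metric, "_mean"))
  metrics <- bind_rows(metrics, summary_rows) |>
    arrange(.data$sample, .data$target, .data$metric, .data$replicate)
  write_results_table(metrics, file.path(output_dir, "metrics.csv"))

  manifest <- list(
    package = "selfiedpcr",
    version = as.character(packageVersion("selfiedpcr")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    config = unclass(config),
    wells = sort(unique(counts$well_id))
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_stage("done: %s", output_dir)
  invisible(list(counts = counts, concentrations = quant, metrics = metrics,
                 manifest = manifest))
}

#' Generate simulated fixture files from a scenario configuration
#'
#' Scenario config (YAML path or list): `type` (`"pair"` or `"panel"`),
#' `seed`, optional `params` overriding [simulation_params()] fields, and
#' for panels `n_replicates`. Writes `amplitudes.csv`, `layout.csv`,
#' `chains.csv`, `truth.json` and a ready-to-use `run.yaml` into
#' `output_dir`.
#'
#' @param config scenario configuration (path or list).
#' @param output_dir output directory (created if needed).
#' @return invisibly, the list of written paths.
#' @export
selfie_simulate <- function(config, output_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  type <- config$type %||% abort("Scenario config needs a `type` (pair/panel).")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  set.seed(seed)

  par_over <- config$params %||% list()
  params <- do.call(simulation_params, par_over)

  if (type == "pair") {
    sim <- simulate_selfie_pair(params,
                                sample_id = config$sample_id %||% "sample",
                                target = config$target %||% "target",
                                include_ntc = TRUE)
    wells <- sim$wells
    chains <- list(default = params$dilution_chain)
    truth <- sim$truth |> select(-"occupancy_plus", -"occupancy_minus")
  } else if (type == "panel") {
    sim <- simulate_tissue_panel(n_replicates = config$n_replicates %||% 3L,
                                 base_params = params)
    wells <- sim$wells
    chains <- sim$chains
    truth <- sim$truth
  } else {
    abort(paste0("Unknown scenario type: ", type))
  }

  layout <- wells |>
    select("well_id", "sample_id", "target", "rt_condition",
           "dilution_chain", "replicate")
  paths <- list(
    amplitudes = file.path(output_dir, "amplitudes.csv"),
    layout = file.path(output_dir, "layout.csv"),
    chains = file.path(output_dir, "chains.csv"),
    truth = file.path(output_dir, "truth.json"),
    run_config = file.path(output_dir, "run.yaml")
  )
  write_amplitude_csv(wells, paths$amplitudes)
  write_plate_layout(layout, paths$layout)
  write_dilution_chains(chains, paths$chains)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  yaml::write_yaml(list(
    amplitude_file = "amplitudes.csv",
    layout_file = "layout.csv",
    chains_file = "chains.csv",
    droplet_volume = params$droplet_volume,
    ci_level = 0.95,
    reference_target = config$reference_target %||%
      (if (type == "panel") "Gsk3b-81" else NULL),
    seed = seed
  ), paths$run_config)
  log_stage("simulated %d wells into %s", nrow(wells), output_dir)
  invisible(paths)
}
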