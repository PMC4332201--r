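# ---- configuration and end-to-end pipeline -------------------------------

#' Read a pipeline configuration
#'
#' A configuration is a YAML file (or an equivalent named list) with
#' top-level keys: `assay` (one of `accumulation`, `viability`,
#' `timelapse`, `if_correlation`), `seed`, optional `outdir`, a `simulate`
#' block of [simulation_config()] overrides, a `segmentation` block
#' (`mode`, `sigma_um`), and optional threshold overrides
#' (`death_threshold_au`, `pi_roi`, `ruleset_reference`).  Every assay
#' threshold has its standard value as the default, so a minimal config is
#' just the assay name.
#'
#' @param config path to a YAML file, or a named list.
#' @return validated config list of class `"pipeline_config"`.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a named list")
  valid <- c("accumulation", "viability", "timelapse", "if_correlation")
  if (is.null(config$assay) || !config$assay %in% valid)
    stop("unknown assay variant '", config$assay %||% "<missing>",
         "'; valid names: ", paste(valid, collapse = ", "))
  config$seed <- as.integer(config$seed %||% 1L)
  config$segmentation <- utils::modifyList(
    list(mode = "spot", sigma_um = 2), config$segmentation %||% list())
  config$death_threshold_au <- config$death_threshold_au %||% 100
  config$pi_roi <- config$pi_roi %||% "cytosol"
  config$ruleset_reference <- config$ruleset_reference %||% "population"
  class(config) <- c("pipeline_config", "list")
  config
}

sim_config_from <- function(config, ...) {
  over <- utils::modifyList(config$simulate %||% list(), list(...))
  over$rng_seed <- over$rng_seed %||% config$seed
  do.call(simulation_config, over)
}

# segment + ROI construction for one field, returning everything downstream
# stages need
segment_field <- function(field, seg_params) {
  seg <- segment_nuclei(field$channels$hoechst, field$pixel_size_um,
                        seg_params)
  rois <- build_cytosol_rois(seg$labels, field$pixel_size_um)
  list(seg = seg, rois = rois)
}

count_flags <- function(flags) {
  f <- unlist(strsplit(flags[flags != ""], ",", fixed = TRUE))
  if (!length(f)) return(data.frame(rule_id = character(), n = integer()))
  t <- table(f)
  data.frame(rule_id = names(t), n = as.integer(t), stringsAsFactors = FALSE)
}

run_accumulation <- function(config) {
  cfg <- sim_config_from(config)
  vehicle_cfg <- sim_config_from(config,
                                 fba_lognormal_mu = log(1e-6),
                                 fba_lognormal_sigma = 0,
                                 debris_rate_per_mm2 = 0,
                                 rng_seed = config$seed + 1L)
  sim <- generate_field(cfg)
  veh <- generate_field(vehicle_cfg)
  sf <- segment_field(sim$field, config$segmentation)
  vf <- segment_field(veh$field, config$segmentation)
  veh_rec <- measure_cells(veh$field, vf$rois, vf$seg$nuclei)
  control_mean <- mean(veh_rec$anion_cytosol_mean)
  rec <- measure_cells(sim$field, sf$rois, sf$seg$nuclei)
  rec <- subtract_backgrounds(rec, sim$field, control_mean_anion = control_mean)
  rec <- apply_exclusions(rec, exclusion_ruleset("accumulation_assay"),
                          sim$field$pixel_size_um,
                          reference = config$ruleset_reference)
  kept <- rec[rec$retained, ]
  mean_fba <- mean(kept$anion_cytosol_mean_corr)
  summary <- data.frame(
    n_segmented = nrow(rec), n_retained = nrow(kept),
    mean_fba_corr = mean_fba,
    cv_fba_pct = coefficient_of_variation(kept$anion_cytosol_mean_corr),
    cv_hoechst_pct = coefficient_of_variation(kept$hoechst_nuclear_mean_corr),
    mean_nuclear_diameter_um = mean(kept$max_feret_um),
    low_signal = mean_fba <= 75)   # annotation: too low for robust scoring
  list(cells = rec, summary = summary, exclusion_census = count_flags(rec$flags),
       labels = sf$seg$labels, truth = sim$truth)
}

run_viability <- function(config) {
  cfg <- sim_config_from(config)
  sim <- generate_field(cfg)
  sf <- segment_field(sim$field, config$segmentation)
  rec <- measure_cells(sim$field, sf$rois, sf$seg$nuclei)
  rec <- subtract_backgrounds(rec, sim$field, control_mean_anion = 0)
  sc <- score_viability(rec, sim$field$pixel_size_um)
  summary <- data.frame(n_segmented = nrow(rec), n_viable = sc$n_viable,
                        true_live = sum(sim$truth$is_cell &
                                          sim$truth$viable_at_t0))
  list(cells = sc$records, summary = summary,
       exclusion_census = count_flags(
         apply_exclusions(rec, exclusion_ruleset("viability_assay"),
                          sim$field$pixel_size_um)$flags),
       labels = sf$seg$labels, truth = sim$truth)
}

run_timelapse <- function(config) {
  cfg <- sim_config_from(config)
  tl <- generate_timelapse(cfg, render = TRUE)
  sf <- segment_field(tl$fields[[1]], config$segmentation)
  rec <- measure_cells(tl$fields[[1]], sf$rois, sf$seg$nuclei)
  rec <- apply_exclusions(rec, exclusion_ruleset("timelapse_assay"),
                          tl$fields[[1]]$pixel_size_um,
                          reference = config$ruleset_reference)
  traces <- link_and_trace(tl$fields, sf$rois,
                           death_threshold_au = config$death_threshold_au,
                           pi_roi = config$pi_roi,
                           frame_interval_min = cfg$frame_interval_min)
  t0 <- attr(traces, "t0")
  # retained cells, viable at frame 1 (not already PI-positive)
  dead_at_start <- vapply(traces, function(tr)
    isTRUE(tr$death_frame == 1L), logical(1))
  ok <- rec$retained & !dead_at_start[rec$label] &
    is.finite(t0$fba_over_hoechst[match(rec$label, t0$label)])
  labs <- rec$label[ok]
  fba0 <- t0$fba_initial[match(labs, t0$label)]
  dead <- vapply(traces[labs], function(tr) !is.na(tr$death_frame) &&
                   tr$death_frame > 1L, logical(1))
  groups <- tertile_death_summary(fba0, dead)
  fold <- tryCatch(fold_fba_dying_vs_surviving(fba0, dead),
                   error = function(e) NA_real_)
  summary <- data.frame(n_segmented = nrow(rec), n_analyzed = length(labs),
                        death_pct_whole = death_fraction(dead),
                        fold_fba_dying_vs_surviving = fold)
  cells <- data.frame(label = labs, fba_initial = fba0,
                      tertile = as.character(stratify_by_fba(fba0)),
                      dead = dead)
  list(cells = cells, summary = summary, groups = groups,
       exclusion_census = count_flags(rec$flags),
       labels = sf$seg$labels, truth = tl$truth, traces = traces)
}

run_if_correlation <- function(config) {
  cfg <- sim_config_from(config)
  sim <- generate_field(cfg)
  sf <- segment_field(sim$field, config$segmentation)
  rec <- measure_cells(sim$field, sf$rois, sf$seg$nuclei)
  rec <- subtract_backgrounds(rec, sim$field, control_mean_anion = 0)
  rec <- apply_exclusions(rec, exclusion_ruleset("accumulation_assay"),
                          sim$field$pixel_size_um,
                          reference = config$ruleset_reference)
  kept <- rec[rec$retained, ]
  # marker is carried in the lysotracker channel slot for this assay
  cc <- correlate_per_cell(kept$anion_cytosol_mean_corr,
                           kept$lysotracker_cytosol_mean_corr)
  summary <- data.frame(n_segmented = nrow(rec), n_retained = nrow(kept),
                        correlation_r = cc$r, correlation_n = cc$n)
  list(cells = rec, summary = summary,
       exclusion_census = count_flags(rec$flags),
       labels = sf$seg$labels, truth = sim$truth)
}

#' Run the full pipeline for one assay variant
#'
#' Executes simulate -> segment -> measure -> exclude -> score ->
#' summarize for the configured assay and, when `outdir` is given, writes
#' a self-describing run directory: `cells.csv`, `summary.csv`,
#' `exclusion_census.csv`, `report.json`, `labels.tif`, and a copy of the
#' resolved configuration (`config.json`).  A fixed `seed` makes the whole
#' run byte-reproducible.
#'
#' @param config path to a YAML config, or a named list
#'   (see [read_pipeline_config()]).
#' @param outdir output directory; `NULL` skips writing.
#' @param seed optional override of the config seed.
#' @return invisibly, the result bundle (list of tables).
#' @export
run_pipeline <- function(config, outdir = NULL, seed = NULL) {
  config <- read_pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  res <- switch(config$assay,
    accumulation = run_accumulation(config),
    viability = run_viability(config),
    timelapse = run_timelapse(config),
    if_correlation = run_if_correlation(config))
  res$assay <- config$assay
  res$seed <- config$seed
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    num <- function(df) { # stable text output: round trip-safe formatting
      for (c in names(df)) if (is.numeric(df[[c]]))
        df[[c]] <- formatC(df[[c]], digits = 12, format = "g")
      df
    }
    utils::write.csv(num(res$cells), file.path(outdir, "cells.csv"),
                     row.names = FALSE)
    utils::write.csv(num(res$summary), file.path(outdir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(res$exclusion_census,
                     file.path(outdir, "exclusion_census.csv"),
                     row.names = FALSE)
    if (!is.null(res$groups))
      utils::write.csv(num(res$groups), file.path(outdir, "groups.csv"),
                       row.names = FALSE)
    write_label_tiff(res$labels, file.path(outdir, "labels.tif"))
    report <- list(assay = config$assay, seed = config$seed,
                   summary = res$summary,
                   exclusion_census = res$exclusion_census)
    if (!is.null(res$groups)) report$groups <- res$groups
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfg_copy <- unclass(config)
    jsonlite::write_json(cfg_copy, file.path(outdir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}
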