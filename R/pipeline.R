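# End-to-end pipeline stages. Each stage writes its tabular outputs, the
# fully resolved configuration, and a short log (package version, seed) to
# the output directory; reruns with the same configuration and seed are
# byte-identical in all tabular outputs.

write_stage_log <- function(out_dir, stage, seed, lines = character(0)) {
  log <- c(
    sprintf("catrace %s", as.character(utils::packageVersion("catrace"))),
    sprintf("stage: %s", stage),
    sprintf("seed: %d", seed),
    lines
  )
  writeLines(log, file.path(out_dir, paste0(stage, ".log")))
  invisible(NULL)
}

resolve_config <- function(config, seed) {
  if (inherits(config, "run_config") && is.null(seed)) config
  else load_run_config(if (inherits(config, "run_config")) unclass(config)
                       else config, seed = seed)
}

#' Simulate a recording to disk
#'
#' Generates ground truth and traces from the `sim` section of the run
#' configuration and writes `traces.csv` (+ sidecar), `ground_truth.tsv`
#' (+ sidecar), the resolved `config.yaml`, and a log.
#'
#' @param config run configuration: YAML path, named list, or
#'   `run_config` (see [load_run_config()]).
#' @param out_dir output directory (created if needed).
#' @param seed optional top-level seed override.
#' @return (invisibly) list with `truth`, `traces`, and output paths.
#' @export
pipeline_simulate <- function(config = NULL, out_dir, seed = NULL) {
  cfg <- resolve_config(config, seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scfg <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
  truth <- simulate_ground_truth(scfg)
  traces <- render_traces(truth)
  tr_path <- file.path(out_dir, "traces.csv")
  gt_path <- file.path(out_dir, "ground_truth.tsv")
  write_traces(traces, tr_path)
  write_ground_truth(truth, gt_path)
  write_run_config(cfg, file.path(out_dir, "config.yaml"))
  write_stage_log(out_dir, "simulate", cfg$seed,
                  c(paste("traces:", tr_path),
                    paste("ground_truth:", gt_path)))
  invisible(list(truth = truth, traces = traces,
                 traces_path = tr_path, ground_truth_path = gt_path))
}

#' Preprocess and detect events from a trace CSV
#'
#' Runs dF/F0 preprocessing and event detection on a trace CSV and writes
#' `events.tsv` (+ sidecar), `roi_stats.tsv`, the resolved config, and a
#' log.
#'
#' @param traces_path trace CSV written by [write_traces()] (or a
#'   `trace_set` object).
#' @inheritParams pipeline_simulate
#' @return (invisibly) list with `dffset`, `events`, and output paths.
#' @export
pipeline_detect <- function(traces_path, config = NULL, out_dir,
                            seed = NULL) {
  cfg <- resolve_config(config, seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  traces <- if (inherits(traces_path, "trace_set")) traces_path
            else read_traces(traces_path)
  pp <- cfg$preprocess
  dffset <- preprocess_traces(traces, percentile = pp$percentile,
                              window_s = pp$window_s,
                              smoothing_window_frames = pp$smoothing_window,
                              robust = pp$robust)
  events <- detect_events(dffset, do.call(detector_params, cfg$detector))
  ev_path <- file.path(out_dir, "events.tsv")
  st_path <- file.path(out_dir, "roi_stats.tsv")
  write_events(events, ev_path)
  write_roi_stats(dffset, st_path)
  write_run_config(cfg, file.path(out_dir, "config.yaml"))
  n_active <- length(unique(events$roi_id))
  write_stage_log(out_dir, "detect", cfg$seed,
                  c(paste("n_events:", nrow(events)),
                    paste("n_active:", n_active)))
  invisible(list(dffset = dffset, events = events,
                 events_path = ev_path, roi_stats_path = st_path))
}

#' Population metrics from an event table
#'
#' Computes the activity summary, event raster, coactivity histogram, and
#' synchrony test; if the configuration has a drug epoch (`sim$drug_time_s`
#' set, or `administration_time_s` given), also the pre/post frequency
#' modulation. Writes `activity.tsv`, `raster.tsv`, `synchrony.tsv`,
#' optionally `drug.tsv`, figures if enabled, the resolved config, and a
#' log.
#'
#' @param events_path events TSV written by [write_events()] (or a
#'   `ca_events` object).
#' @param duration_s recording duration in seconds (defaults to the sim
#'   section's duration).
#' @param administration_time_s drug time; defaults to the sim section's
#'   `drug_time_s` (possibly absent).
#' @inheritParams pipeline_simulate
#' @return (invisibly) list with `activity`, `raster`, `synchrony`, and
#'   `drug` (NULL when no drug epoch).
#' @export
pipeline_metrics <- function(events_path, config = NULL, out_dir,
                             seed = NULL, duration_s = NULL,
                             administration_time_s = NULL) {
  cfg <- resolve_config(config, seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  events <- if (inherits(events_path, "ca_events")) events_path
            else read_events(events_path)
  if (is.null(duration_s)) duration_s <- cfg$sim$duration_s
  if (is.null(administration_time_s))
    administration_time_s <- cfg$sim$drug_time_s
  m <- cfg$metrics
  activity <- summarize_activity(events,
                                 observation_window_s = duration_s,
                                 min_events = m$min_events)
  raster <- build_raster(events, bin_width_s = m$bin_width_s,
                         duration_s = duration_s)
  sync <- synchrony_test(raster, n_shuffles = m$n_shuffles, seed = cfg$seed)
  drug <- NULL
  if (!is.null(administration_time_s)) {
    drug <- drug_modulation(events, administration_time_s,
                            pre_window = m$drug_pre_window,
                            post_window = m$drug_post_window,
                            duration_s = duration_s)
    utils::write.table(
      data.frame(administration_time_s = drug$administration_time_s,
                 freq_pre = drug$freq_pre, freq_post = drug$freq_post,
                 normalized_frequency = drug$normalized_frequency,
                 undefined = drug$undefined),
      file.path(out_dir, "drug.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(activity$per_roi, file.path(out_dir, "activity.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(n_total = activity$n_total, n_active = activity$n_active,
               percent_active = activity$percent_active,
               sync_index = sync$sync_index, sync_p = sync$p_value),
    file.path(out_dir, "summary.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cbind(roi_id = rownames(raster$bins),
                           as.data.frame(raster$bins)),
                     file.path(out_dir, "raster.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (isTRUE(cfg$io$figures)) {
    grDevices::png(file.path(out_dir, "raster.png"), width = 900,
                   height = 600)
    plot(raster)
    grDevices::dev.off()
  }
  write_run_config(cfg, file.path(out_dir, "config.yaml"))
  write_stage_log(out_dir, "metrics", cfg$seed,
                  c(sprintf("percent_active: %g", activity$percent_active),
                    sprintf("sync_p: %g", sync$p_value)))
  invisible(list(activity = activity, raster = raster, synchrony = sync,
                 drug = drug))
}

#' Run the full pipeline
#'
#' simulate -> detect -> metrics in one output directory.
#'
#' @inheritParams pipeline_simulate
#' @return (invisibly) list with the stage results (`sim`, `detect`,
#'   `metrics`).
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = NULL) {
  cfg <- resolve_config(config, seed)
  sim <- pipeline_simulate(cfg, out_dir)
  det <- pipeline_detect(sim$traces_path, cfg, out_dir)
  met <- pipeline_metrics(det$events_path, cfg, out_dir)
  invisible(list(sim = sim, detect = det, metrics = met))
}
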