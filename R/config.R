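# Run configuration: one YAML file with sections mirroring the pipeline
# stages. Unknown keys are rejected; every run writes back the fully
# resolved configuration (defaults filled in) next to its outputs.

run_config_defaults <- function() {
  list(
    seed = 1L,
    sim = as.list(formals(sim_config))[
      setdiff(names(formals(sim_config)), "seed")],
    preprocess = list(percentile = 8, window_s = 30,
                      smoothing_window = 1, robust = TRUE),
    detector = list(k_peak = 0.5, k_rise = 4, min_separation_frames = 5,
                    min_rise_frames = 3, rise_criterion = "derivative"),
    metrics = list(bin_width_s = 1, min_events = 1, n_shuffles = 500,
                   drug_pre_window = c(-20, 0),
                   drug_post_window = c(10, 30)),
    io = list(figures = FALSE)
  )
}

merge_section <- function(defaults, user, section) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown key(s) in `", section, "`: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  defaults[names(user)] <- user
  defaults
}

#' Load and resolve a run configuration
#'
#' Reads a YAML run configuration with sections `sim`, `preprocess`,
#' `detector`, `metrics`, `io` and a top-level `seed`, fills in defaults,
#' and rejects unknown keys. `config = NULL` returns the full default
#' configuration.
#'
#' @param path YAML file, a named list, or `NULL` for defaults.
#' @param seed optional override for the top-level seed.
#' @return Object of class `run_config` (nested named list, fully
#'   resolved).
#' @export
load_run_config <- function(path = NULL, seed = NULL) {
  user <- if (is.null(path)) list()
          else if (is.character(path)) yaml::read_yaml(path)
          else if (is.list(path)) path
          else stop("`path` must be a file path, a list, or NULL",
                    call. = FALSE)
  def <- run_config_defaults()
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    stop("unknown top-level key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- def
  for (s in c("sim", "preprocess", "detector", "metrics", "io"))
    cfg[[s]] <- merge_section(def[[s]], user[[s]], s)
  if (!is.null(user$seed)) cfg$seed <- user$seed
  if (!is.null(seed)) cfg$seed <- seed
  cfg$seed <- as.integer(cfg$seed)
  # the sim section's formal defaults may still be language objects; force
  cfg$sim <- lapply(cfg$sim, function(v) if (is.language(v)) eval(v) else v)
  # validate by construction
  validate_sim_config(do.call(sim_config, c(cfg$sim, list(seed = cfg$seed))))
  do.call(detector_params, cfg$detector)
  structure(cfg, class = "run_config")
}

#' Write a resolved run configuration
#'
#' @param config a `run_config`.
#' @param path output YAML file.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
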