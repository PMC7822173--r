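# Synthetic fluorescence-trace generator with known ground truth.
#
# The generator emulates the statistical structure of somatic calcium-dye
# recordings: per-ROI Poisson event trains, an optional shared "network"
# event stream producing population synchrony, convolution with a fast-dye
# indicator kernel, a multiplicative baseline with slow sinusoidal drift,
# additive Gaussian noise, and an optional drug epoch that thins the event
# rate after administration (a sodium-channel-blocker analogue).

#' Simulation configuration
#'
#' Builds and validates the parameter set for the synthetic trace generator.
#' Defaults describe a 20 frames/s recording of a moderately active culture.
#'
#' @param n_rois number of ROIs (cells).
#' @param duration_s recording duration in seconds.
#' @param frame_rate_hz acquisition rate in frames per second (default 20,
#'   the rate of the EMCCD recordings this generator emulates).
#' @param base_rate_hz per-ROI calcium-event rate in Hz.
#' @param sync_fraction fraction of each ROI's events drawn from the shared
#'   network-event stream, in \[0, 1\]. 0 gives fully independent cells.
#' @param network_rate_hz rate of the shared network-event stream in Hz.
#' @param jitter_s SD (seconds) of per-ROI timing jitter around each shared
#'   network event.
#' @param kernel_rise_s,kernel_decay_s rise and decay time constants
#'   (seconds) of the difference-of-exponentials indicator kernel; decay
#'   must exceed rise.
#' @param amplitude peak transient amplitude in dF/F0 units.
#' @param f0_mean,f0_cv mean baseline fluorescence (arbitrary units) and its
#'   across-ROI coefficient of variation.
#' @param drift_amp,drift_period_s relative amplitude and period (seconds)
#'   of the slow sinusoidal baseline drift.
#' @param noise_sd additive Gaussian noise SD in raw fluorescence units.
#' @param drug_time_s administration time in seconds, or `NULL` for no drug
#'   epoch.
#' @param post_drug_rate_factor multiplier applied to both event streams
#'   after `drug_time_s` (0 = complete blockade, 1 = vehicle).
#' @param seed integer RNG seed; the simulation is bit-reproducible from
#'   (config, seed).
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_rois = 20,
                       duration_s = 300,
                       frame_rate_hz = 20,
                       base_rate_hz = 0.1,
                       sync_fraction = 0,
                       network_rate_hz = 0.05,
                       jitter_s = 0.1,
                       kernel_rise_s = 0.05,
                       kernel_decay_s = 1.0,
                       amplitude = 0.5,
                       f0_mean = 100,
                       f0_cv = 0.1,
                       drift_amp = 0.02,
                       drift_period_s = 120,
                       noise_sd = 1,
                       drug_time_s = NULL,
                       post_drug_rate_factor = 1,
                       seed = 1L) {
  cfg <- list(
    n_rois = n_rois, duration_s = duration_s, frame_rate_hz = frame_rate_hz,
    base_rate_hz = base_rate_hz, sync_fraction = sync_fraction,
    network_rate_hz = network_rate_hz, jitter_s = jitter_s,
    kernel_rise_s = kernel_rise_s, kernel_decay_s = kernel_decay_s,
    amplitude = amplitude, f0_mean = f0_mean, f0_cv = f0_cv,
    drift_amp = drift_amp, drift_period_s = drift_period_s,
    noise_sd = noise_sd, drug_time_s = drug_time_s,
    post_drug_rate_factor = post_drug_rate_factor, seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check_scalar(cfg$n_rois, "n_rois", min = 1, integer = TRUE)
  check_scalar(cfg$duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_scalar(cfg$frame_rate_hz, "frame_rate_hz", min = 0, strict_min = TRUE)
  check_scalar(cfg$base_rate_hz, "base_rate_hz", min = 0)
  check_scalar(cfg$sync_fraction, "sync_fraction", min = 0, max = 1)
  check_scalar(cfg$network_rate_hz, "network_rate_hz", min = 0)
  check_scalar(cfg$jitter_s, "jitter_s", min = 0)
  check_scalar(cfg$kernel_rise_s, "kernel_rise_s", min = 0, strict_min = TRUE)
  check_scalar(cfg$kernel_decay_s, "kernel_decay_s",
               min = cfg$kernel_rise_s, strict_min = TRUE)
  check_scalar(cfg$amplitude, "amplitude", min = 0)
  check_scalar(cfg$f0_mean, "f0_mean", min = 0, strict_min = TRUE)
  check_scalar(cfg$f0_cv, "f0_cv", min = 0)
  check_scalar(cfg$drift_amp, "drift_amp", min = 0)
  check_scalar(cfg$drift_period_s, "drift_period_s", min = 0,
               strict_min = TRUE)
  check_scalar(cfg$noise_sd, "noise_sd", min = 0)
  check_scalar(cfg$drug_time_s, "drug_time_s", min = 0, allow_null = TRUE,
               max = cfg$duration_s)
  check_scalar(cfg$post_drug_rate_factor, "post_drug_rate_factor", min = 0)
  check_scalar(cfg$seed, "seed", integer = TRUE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_rois, "ROIs,", x$duration_s, "s at",
      x$frame_rate_hz, "fps;",
      "base rate", x$base_rate_hz, "Hz, sync_fraction", x$sync_fraction)
  if (!is.null(x$drug_time_s))
    cat(";", "drug at", x$drug_time_s, "s (factor",
        x$post_drug_rate_factor, ")")
  cat("; seed", x$seed, "\n")
  invisible(x)
}

# Homogeneous Poisson process on [0, duration): count then sorted uniforms.
rpoisson_times <- function(rate, duration) {
  n <- stats::rpois(1L, rate * duration)
  if (n == 0L) return(numeric(0))
  sort(stats::runif(n, 0, duration))
}

#' Simulate ground-truth event times
#'
#' Draws shared network events as a homogeneous Poisson process and, for
#' each ROI, the union of an independent Poisson stream at
#' `base_rate_hz * (1 - sync_fraction)` and each network event included
#' independently with probability `sync_fraction`, jittered by
#' `Normal(0, jitter_s)` and clipped to the recording. If a drug epoch is
#' configured, events after `drug_time_s` are thinned: each survives with
#' probability `post_drug_rate_factor`.
#'
#' @param config a [sim_config()].
#' @return Object of class `ground_truth`: list with `event_times_s`
#'   (per-ROI sorted numeric vectors), `network_times_s`, and `config`.
#' @export
simulate_ground_truth <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, 1L), {
    dur <- config$duration_s
    eps <- 1 / (2 * config$frame_rate_hz) * 1e-6
    network <- rpoisson_times(config$network_rate_hz, dur)
    indep_rate <- config$base_rate_hz * (1 - config$sync_fraction)
    events <- vector("list", config$n_rois)
    for (r in seq_len(config$n_rois)) {
      own <- rpoisson_times(indep_rate, dur)
      shared <- numeric(0)
      if (length(network) > 0 && config$sync_fraction > 0) {
        take <- stats::runif(length(network)) < config$sync_fraction
        shared <- network[take]
        if (length(shared) > 0 && config$jitter_s > 0)
          shared <- shared + stats::rnorm(length(shared), 0, config$jitter_s)
        shared <- pmin(pmax(shared, 0), dur - eps)
      }
      ev <- sort(c(own, shared))
      if (!is.null(config$drug_time_s)) {
        post <- ev > config$drug_time_s
        if (any(post)) {
          keep <- !post
          keep[post] <- stats::runif(sum(post)) < config$post_drug_rate_factor
          ev <- ev[keep]
        }
      }
      events[[r]] <- ev
    }
    structure(
      list(event_times_s = events, network_times_s = network,
           config = config),
      class = "ground_truth"
    )
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  counts <- lengths(x$event_times_s)
  cat("<ground_truth>", length(counts), "ROIs;",
      sum(counts), "events (mean", round(mean(counts), 2), "per ROI);",
      length(x$network_times_s), "network events\n")
  invisible(x)
}

#' True events as an event table
#'
#' Converts simulated ground truth into a `ca_events` table (onset = true
#' event time; peak amplitude unknown), so population metrics can be
#' computed directly on the simulated truth.
#'
#' @param truth a `ground_truth` object.
#' @return a [ca_events()] object.
#' @export
ground_truth_events <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  roi_ids <- sprintf("roi%03d", seq_along(truth$event_times_s))
  df <- data.frame(
    roi_id = as.character(rep(roi_ids, lengths(truth$event_times_s))),
    onset_time_s = as.numeric(unlist(truth$event_times_s,
                                     use.names = FALSE))
  )
  ca_events(df, truth$config$frame_rate_hz, roi_ids = roi_ids)
}

#' Calcium indicator kernel
#'
#' Difference-of-exponentials impulse response
#' `(1 - exp(-t/rise)) * exp(-t/decay)` normalized to unit peak; zero for
#' `t < 0`.
#'
#' @param t time in seconds (vectorized).
#' @param rise_s,decay_s time constants in seconds, `decay_s > rise_s > 0`.
#' @return kernel values in \[0, 1\].
#' @export
calcium_kernel <- function(t, rise_s = 0.05, decay_s = 1.0) {
  stopifnot(rise_s > 0, decay_s > rise_s)
  t_peak <- rise_s * log(1 + decay_s / rise_s)
  peak <- (1 - exp(-t_peak / rise_s)) * exp(-t_peak / decay_s)
  out <- ifelse(t < 0, 0, (1 - exp(-t / rise_s)) * exp(-t / decay_s) / peak)
  out
}

#' Render fluorescence traces from ground truth
#'
#' Each ROI's trace is
#' `F0 * (1 + drift(t)) * (1 + sum_events amplitude * kernel(t - t_e)) +
#' noise`. Transients superpose linearly; event times map to frames by
#' `floor(t * frame_rate)`. Deterministic given the config seed.
#'
#' @param truth a [simulate_ground_truth()] result.
#' @return Object of class `trace_set`: list with `fluorescence`
#'   (ROIs x frames matrix), `frame_rate_hz`, `roi_ids`.
#' @export
render_traces <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  cfg <- truth$config
  fr <- cfg$frame_rate_hz
  n_frames <- round(cfg$duration_s * fr)
  n_rois <- cfg$n_rois
  # kernel sampled on the frame grid until it has decayed to < 1e-4 of peak
  k_len <- max(2L, ceiling((cfg$kernel_decay_s * 10 + cfg$kernel_rise_s) * fr))
  kernel <- calcium_kernel(seq_len(k_len) / fr - 1 / fr,
                           cfg$kernel_rise_s, cfg$kernel_decay_s)
  t_grid <- (seq_len(n_frames) - 1) / fr
  drift <- if (cfg$drift_amp > 0) {
    cfg$drift_amp * sin(2 * pi * t_grid / cfg$drift_period_s)
  } else rep(0, n_frames)

  with_seed(derive_seed(cfg$seed, 2L), {
    sdlog <- sqrt(log(1 + cfg$f0_cv^2))
    f0 <- cfg$f0_mean * exp(stats::rnorm(n_rois, -sdlog^2 / 2, sdlog))
    mat <- matrix(0, nrow = n_rois, ncol = n_frames)
    for (r in seq_len(n_rois)) {
      sig <- rep(0, n_frames)
      for (te in truth$event_times_s[[r]]) {
        f <- floor(te * fr) + 1L
        if (f > n_frames) next
        idx <- f:min(n_frames, f + k_len - 1L)
        sig[idx] <- sig[idx] + cfg$amplitude * kernel[seq_along(idx)]
      }
      mat[r, ] <- f0[r] * (1 + drift) * (1 + sig)
    }
    if (cfg$noise_sd > 0)
      mat <- mat + matrix(stats::rnorm(n_rois * n_frames, 0, cfg$noise_sd),
                          nrow = n_rois)
    trace_set(mat, fr, roi_ids = sprintf("roi%03d", seq_len(n_rois)))
  })
}

#' Construct a trace set
#'
#' Container for an ROI-by-frame raw fluorescence matrix with its frame
#' rate — the extracted-trace input of the pipeline.
#'
#' @param fluorescence numeric matrix, ROIs in rows, frames in columns.
#' @param frame_rate_hz frames per second.
#' @param roi_ids optional character labels (default `roi001`, ...).
#' @return Object of class `trace_set`.
#' @export
trace_set <- function(fluorescence, frame_rate_hz, roi_ids = NULL) {
  if (!is.matrix(fluorescence) || !is.numeric(fluorescence))
    stop_field("fluorescence", "must be a numeric matrix (ROIs x frames)")
  if (anyNA(fluorescence))
    stop_field("fluorescence", "must not contain missing values")
  check_scalar(frame_rate_hz, "frame_rate_hz", min = 0, strict_min = TRUE)
  if (is.null(roi_ids)) roi_ids <- sprintf("roi%03d", seq_len(nrow(fluorescence)))
  if (length(roi_ids) != nrow(fluorescence))
    stop_field("roi_ids", "length must equal nrow(fluorescence)")
  rownames(fluorescence) <- roi_ids
  structure(list(fluorescence = fluorescence,
                 frame_rate_hz = frame_rate_hz,
                 roi_ids = as.character(roi_ids)),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat("<trace_set>", nrow(x$fluorescence), "ROIs x",
      ncol(x$fluorescence), "frames at", x$frame_rate_hz, "fps (",
      round(ncol(x$fluorescence) / x$frame_rate_hz, 1), "s )\n")
  invisible(x)
}

#' @export
plot.trace_set <- function(x, rois = seq_len(min(5, nrow(x$fluorescence))),
                           offset = NULL, ...) {
  mat <- x$fluorescence[rois, , drop = FALSE]
  t <- (seq_len(ncol(mat)) - 1) / x$frame_rate_hz
  if (is.null(offset)) offset <- max(apply(mat, 1, function(z) diff(range(z))))
  graphics::plot(range(t), c(0, offset * nrow(mat)), type = "n",
                 xlab = "time (s)", ylab = "fluorescence (offset)", ...)
  for (i in seq_len(nrow(mat)))
    graphics::lines(t, mat[i, ] - min(mat[i, ]) + (i - 1) * offset)
  invisible(x)
}
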