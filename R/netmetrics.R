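# Population-level readouts: percent active cells, event rasters,
# coactivity histograms, a circular-shift permutation test for network
# synchrony, and pre/post-administration frequency modulation.

#' Summarize population activity
#'
#' A cell is "active" if it has at least `min_events` detected events in
#' the observation window; the headline statistic is the percentage of
#' active cells among all cells in the field of view (which may exceed the
#' number of ROIs with events, e.g. when the denominator is a nuclear
#' count).
#'
#' @param events a `ca_events` object.
#' @param n_total_rois total number of cells in the field of view;
#'   defaults to the number of ROI labels carried by `events`.
#' @param observation_window_s window length in seconds used for the
#'   active-cell call and the per-ROI frequencies; defaults to the time of
#'   the last event (rounded up) or 60 s if there are none.
#' @param min_events minimum event count for a cell to count as active
#'   (default 1).
#' @return Object of class `activity_summary`: list with `per_roi`
#'   (data.frame: roi_id, n_events, freq_per_min, active), `n_total`,
#'   `n_active`, `percent_active`.
#' @export
summarize_activity <- function(events, n_total_rois = NULL,
                               observation_window_s = NULL, min_events = 1) {
  stopifnot(inherits(events, "ca_events"))
  check_scalar(min_events, "min_events", min = 1, integer = TRUE)
  roi_ids <- attr(events, "roi_ids")
  if (is.null(n_total_rois)) n_total_rois <- length(roi_ids)
  if (n_total_rois < length(unique(events$roi_id)))
    stop_field("n_total_rois", "fewer than the number of ROIs with events")
  if (is.null(observation_window_s))
    observation_window_s <- if (nrow(events)) max(ceiling(events$onset_time_s), 1) else 60
  check_scalar(observation_window_s, "observation_window_s",
               min = 0, strict_min = TRUE)
  in_win <- events$onset_time_s < observation_window_s
  counts <- table(factor(events$roi_id[in_win], levels = roi_ids))
  per_roi <- data.frame(
    roi_id = roi_ids,
    n_events = as.integer(counts),
    freq_per_min = as.numeric(counts) / (observation_window_s / 60),
    active = as.integer(counts) >= min_events,
    row.names = NULL
  )
  n_active <- sum(per_roi$active)
  structure(list(per_roi = per_roi, n_total = n_total_rois,
                 n_active = n_active,
                 percent_active = 100 * n_active / n_total_rois,
                 observation_window_s = observation_window_s,
                 min_events = as.integer(min_events)),
            class = "activity_summary")
}

#' @export
print.activity_summary <- function(x, ...) {
  cat("<activity_summary>", x$n_active, "of", x$n_total, "cells active (",
      sprintf("%.1f%%", x$percent_active), ") in",
      x$observation_window_s, "s\n")
  cat("  mean frequency of active cells:",
      sprintf("%.2f events/min",
              mean(x$per_roi$freq_per_min[x$per_roi$active])), "\n")
  invisible(x)
}

#' Build a binary event raster
#'
#' Bins event onsets into half-open time bins `[b*w, (b+1)*w)`; entry
#' (ROI, bin) is 1 if that ROI has at least one onset in the bin.
#'
#' @param events a `ca_events` object.
#' @param bin_width_s bin width in seconds (default 1).
#' @param duration_s recording duration in seconds; every event must fall
#'   inside it.
#' @param start_time_s raster start time (default 0).
#' @return Object of class `event_raster`: list with `bins` (0/1 matrix,
#'   ROIs x bins), `bin_width_s`, `start_time_s`.
#' @export
build_raster <- function(events, bin_width_s = 1, duration_s,
                         start_time_s = 0) {
  stopifnot(inherits(events, "ca_events"))
  check_scalar(bin_width_s, "bin_width_s", min = 0, strict_min = TRUE)
  check_scalar(duration_s, "duration_s", min = 0, strict_min = TRUE)
  if (nrow(events) && any(events$onset_time_s >= duration_s |
                          events$onset_time_s < start_time_s))
    stop("events fall outside [start_time_s, duration_s)", call. = FALSE)
  roi_ids <- attr(events, "roi_ids")
  n_bins <- ceiling((duration_s - start_time_s) / bin_width_s)
  bins <- matrix(0L, nrow = length(roi_ids), ncol = n_bins,
                 dimnames = list(roi_ids, NULL))
  if (nrow(events)) {
    b <- floor((events$onset_time_s - start_time_s) / bin_width_s) + 1L
    r <- match(events$roi_id, roi_ids)
    bins[cbind(r, b)] <- 1L
  }
  structure(list(bins = bins, bin_width_s = bin_width_s,
                 start_time_s = start_time_s),
            class = "event_raster")
}

#' @export
print.event_raster <- function(x, ...) {
  cat("<event_raster>", nrow(x$bins), "ROIs x", ncol(x$bins), "bins of",
      x$bin_width_s, "s;", sum(x$bins), "filled\n")
  invisible(x)
}

#' Raster plot with coactivity histogram
#'
#' Event raster (one row per ROI, a dot per occupied bin) over a lower
#' panel showing the fraction of coactive ROIs per time bin.
#'
#' @param x an `event_raster`.
#' @param ... passed to the raster panel's `plot`.
#' @export
plot.event_raster <- function(x, ...) {
  co <- coactivity_histogram(x)
  t <- x$start_time_s + (seq_len(ncol(x$bins)) - 0.5) * x$bin_width_s
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op), add = TRUE)
  idx <- which(x$bins == 1L, arr.ind = TRUE)
  graphics::plot(t[idx[, 2]], idx[, 1], pch = 16, cex = 0.4,
                 xlim = range(t), ylim = c(0.5, nrow(x$bins) + 0.5),
                 xlab = "", ylab = "ROI", ...)
  graphics::par(mar = c(4, 4, 0.5, 1))
  graphics::plot(t, co, type = "h", xlab = "time (s)",
                 ylab = "coactive fraction", ylim = c(0, 1))
  invisible(x)
}

#' Coactivity histogram
#'
#' Per-bin fraction of ROIs with an event: column sums of the raster
#' divided by the number of ROIs.
#'
#' @param raster an `event_raster`.
#' @return numeric vector of per-bin fractions in \[0, 1\].
#' @export
coactivity_histogram <- function(raster) {
  stopifnot(inherits(raster, "event_raster"))
  if (nrow(raster$bins) == 0L) stop("empty raster", call. = FALSE)
  unname(colSums(raster$bins) / nrow(raster$bins))
}

#' Permutation test for network synchrony
#'
#' The synchrony statistic is the maximum per-bin coactive fraction (a
#' population burst shows up as a bin where many ROIs fire together). The
#' null distribution is built by circularly time-shifting each ROI's row
#' independently — preserving per-ROI event counts and within-ROI
#' structure while destroying cross-ROI alignment — and the p-value is
#' `(1 + #(null >= observed)) / (1 + n_shuffles)`.
#'
#' @param raster an `event_raster` with at least 2 ROIs.
#' @param n_shuffles number of circular-shift surrogates (>= 100; default
#'   500).
#' @param seed integer seed for the shuffle stream.
#' @return Object of class `synchrony_result`: list with
#'   `coactivity_fraction`, `sync_index`, `null_quantiles`, `p_value`,
#'   `n_shuffles`, `seed`.
#' @export
synchrony_test <- function(raster, n_shuffles = 500, seed = 1L) {
  stopifnot(inherits(raster, "event_raster"))
  if (nrow(raster$bins) < 2L)
    stop("synchrony test needs at least 2 ROIs", call. = FALSE)
  check_scalar(n_shuffles, "n_shuffles", min = 100, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  bins <- raster$bins
  n_rois <- nrow(bins); n_bins <- ncol(bins)
  co <- coactivity_histogram(raster)
  obs <- max(co)
  null_max <- with_seed(derive_seed(seed, 3L), {
    vapply(seq_len(n_shuffles), function(s) {
      shifts <- sample.int(n_bins, n_rois, replace = TRUE) - 1L
      tot <- numeric(n_bins)
      for (r in seq_len(n_rois)) {
        if (shifts[r] == 0L) tot <- tot + bins[r, ]
        else tot <- tot + bins[r, c((n_bins - shifts[r] + 1L):n_bins,
                                    1L:(n_bins - shifts[r]))]
      }
      max(tot) / n_rois
    }, numeric(1))
  })
  structure(list(
    coactivity_fraction = co,
    sync_index = obs,
    null_quantiles = stats::quantile(null_max, c(0.5, 0.95, 0.99)),
    null_mean = mean(null_max),
    p_value = (1 + sum(null_max >= obs)) / (1 + n_shuffles),
    n_shuffles = as.integer(n_shuffles),
    seed = as.integer(seed)
  ), class = "synchrony_result")
}

#' @export
print.synchrony_result <- function(x, ...) {
  cat("<synchrony_result> sync index (max coactive fraction):",
      signif(x$sync_index, 3), "\n")
  cat("  null 95th percentile:", signif(x$null_quantiles[["95%"]], 3),
      " p =", signif(x$p_value, 3), "(", x$n_shuffles, "shuffles )\n")
  invisible(x)
}

#' Pre/post-administration frequency modulation
#'
#' Pooled population event frequency (events/min summed over ROIs) in a
#' window before and a window after drug administration, and their ratio.
#' Windows are given relative to the administration time; the default
#' post window of 10-30 s after administration mirrors standard blocker
#' assays, and the pre window is the 20 s immediately before.
#'
#' @param events a `ca_events` object.
#' @param administration_time_s drug administration time in seconds.
#' @param pre_window,post_window length-2 numeric `(start, end)` offsets
#'   in seconds relative to administration; pre must end at or before 0,
#'   post must start after 0, and they must not overlap.
#' @param duration_s recording duration; both windows must fall inside it.
#' @return Object of class `drug_epoch`: list with
#'   `administration_time_s`, `pre_window_s`, `post_window_s`, `freq_pre`,
#'   `freq_post` (events/min, pooled), `normalized_frequency`
#'   (post / pre; `NA` with `undefined = TRUE` when the pre frequency is
#'   zero).
#' @export
drug_modulation <- function(events, administration_time_s,
                            pre_window = c(-20, 0), post_window = c(10, 30),
                            duration_s = NULL) {
  stopifnot(inherits(events, "ca_events"))
  check_scalar(administration_time_s, "administration_time_s", min = 0)
  if (length(pre_window) != 2L || diff(pre_window) <= 0)
    stop_field("pre_window", "must be (start, end) with end > start")
  if (length(post_window) != 2L || diff(post_window) <= 0)
    stop_field("post_window", "must be (start, end) with end > start")
  if (pre_window[2] > 0)
    stop_field("pre_window", "must end at or before administration")
  if (post_window[1] <= 0)
    stop_field("post_window", "must start after administration")
  if (pre_window[2] > post_window[1])
    stop("pre and post windows overlap", call. = FALSE)
  abs_pre <- administration_time_s + pre_window
  abs_post <- administration_time_s + post_window
  if (abs_pre[1] < 0)
    stop("pre window starts before the recording", call. = FALSE)
  if (!is.null(duration_s) && abs_post[2] > duration_s)
    stop("post window extends beyond the recording", call. = FALSE)
  count_in <- function(w)
    sum(events$onset_time_s >= w[1] & events$onset_time_s < w[2])
  freq_pre <- count_in(abs_pre) / (diff(abs_pre) / 60)
  freq_post <- count_in(abs_post) / (diff(abs_post) / 60)
  undefined <- freq_pre == 0
  structure(list(
    administration_time_s = administration_time_s,
    pre_window_s = abs_pre, post_window_s = abs_post,
    freq_pre = freq_pre, freq_post = freq_post,
    normalized_frequency = if (undefined) NA_real_ else freq_post / freq_pre,
    undefined = undefined
  ), class = "drug_epoch")
}

#' @export
print.drug_epoch <- function(x, ...) {
  cat("<drug_epoch> administration at", x$administration_time_s, "s\n")
  cat(sprintf("  pre  [%g, %g) s: %.2f events/min\n",
              x$pre_window_s[1], x$pre_window_s[2], x$freq_pre))
  cat(sprintf("  post [%g, %g) s: %.2f events/min\n",
              x$post_window_s[1], x$post_window_s[2], x$freq_post))
  if (x$undefined) cat("  normalized frequency: undefined (no pre events)\n")
  else cat(sprintf("  normalized frequency: %.3f\n", x$normalized_frequency))
  invisible(x)
}
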