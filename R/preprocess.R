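# Raw fluorescence -> dF/F0, smoothed first derivative, and robust
# baseline-fluctuation statistics. The detector expresses its thresholds in
# units of these baseline SDs.

#' Estimate per-ROI baseline fluorescence F0
#'
#' Takes a low percentile of each ROI's trace in overlapping windows (50%
#' overlap) and aggregates the window values by the median, giving one
#' baseline scalar per ROI. A low percentile selects quiescent frames;
#' the median across windows resists slow drift.
#'
#' @param traces a [trace_set()].
#' @param percentile window percentile in (0, 50); default 8.
#' @param window_s window length in seconds (default 30); must not exceed
#'   the recording.
#' @return named numeric vector of baselines, one per ROI, all > 0.
#' @export
estimate_f0 <- function(traces, percentile = 8, window_s = 30) {
  stopifnot(inherits(traces, "trace_set"))
  check_scalar(percentile, "percentile", min = 0, max = 50,
               strict_min = TRUE, strict_max = TRUE)
  mat <- traces$fluorescence
  if (any(mat <= 0))
    stop("fluorescence must be strictly positive to define F0", call. = FALSE)
  n <- ncol(mat)
  w <- round(window_s * traces$frame_rate_hz)
  if (w > n)
    stop_field("window_s", "window exceeds the recording duration")
  w <- max(1L, w)
  starts <- unique(c(seq(1L, n - w + 1L, by = max(1L, w %/% 2L)), n - w + 1L))
  f0 <- apply(mat, 1, function(x) {
    qs <- vapply(starts, function(s)
      stats::quantile(x[s:(s + w - 1L)], percentile / 100, names = FALSE),
      numeric(1))
    stats::median(qs)
  })
  names(f0) <- traces$roi_ids
  f0
}

#' Compute dF/F0
#'
#' `(F - F0) / F0` per ROI; the dimensionless working signal of the
#' pipeline.
#'
#' @param traces a [trace_set()].
#' @param f0 per-ROI baseline vector, all > 0 (see [estimate_f0()]).
#' @return numeric matrix of the same shape as the input fluorescence.
#' @export
compute_dff <- function(traces, f0) {
  stopifnot(inherits(traces, "trace_set"))
  if (length(f0) != nrow(traces$fluorescence))
    stop_field("f0", "length must equal the number of ROIs")
  if (any(!is.finite(f0)) || any(f0 <= 0))
    stop_field("f0", "baselines must be finite and > 0")
  sweep(sweep(traces$fluorescence, 1, f0, "-"), 1, f0, "/")
}

# Moving average with full-width window in the interior; edges use the
# largest symmetric window that fits, so no frames are dropped.
moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- (window - 1L) %/% 2L
  i <- seq_len(n)
  h <- pmin(half, i - 1L, n - i)
  (cs[i + h + 1L] - cs[i - h]) / (2 * h + 1)
}

#' Smooth and differentiate dF/F0
#'
#' Moving-average smoothing of odd width `window_frames`, then a central
#' first difference per frame (one-sided at the ends). The derivative is in
#' dF/F0 units per frame.
#'
#' @param dff numeric matrix (ROIs x frames) or vector.
#' @param window_frames odd smoothing width in frames, >= 1.
#' @return matrix (or vector) of derivatives, same shape as `dff`.
#' @export
smooth_and_differentiate <- function(dff, window_frames = 5) {
  check_scalar(window_frames, "window_frames", min = 1, integer = TRUE)
  if (window_frames %% 2 == 0)
    stop_field("window_frames", "must be odd")
  vec <- is.null(dim(dff))
  if (vec) dff <- matrix(dff, nrow = 1)
  n <- ncol(dff)
  if (window_frames > n)
    stop_field("window_frames", "smoothing window longer than the trace")
  if (n < 2)
    stop("need at least 2 frames to differentiate", call. = FALSE)
  out <- t(apply(dff, 1, function(x) {
    s <- moving_average(x, window_frames)
    d <- numeric(n)
    d[1] <- s[2] - s[1]
    d[n] <- s[n] - s[n - 1]
    if (n > 2) d[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) / 2
    d
  }))
  if (vec) out[1, ] else out
}

#' Baseline-fluctuation SD
#'
#' Per-ROI spread of baseline fluctuations. The robust default is
#' `1.4826 * MAD` about the median, which is insensitive to sparse
#' transients; `robust = FALSE` gives the ordinary SD for sensitivity
#' analysis.
#'
#' @param signal numeric matrix (ROIs x frames) or vector with >= 30
#'   frames.
#' @param robust use the MAD-based estimator (default `TRUE`).
#' @return numeric vector of SDs, one per ROI.
#' @export
estimate_baseline_sd <- function(signal, robust = TRUE) {
  vec <- is.null(dim(signal))
  if (vec) signal <- matrix(signal, nrow = 1)
  if (ncol(signal) < 30)
    stop("need at least 30 frames to estimate baseline fluctuations",
         call. = FALSE)
  out <- if (robust) {
    apply(signal, 1, stats::mad)           # 1.4826 * median |x - median|
  } else {
    apply(signal, 1, stats::sd)
  }
  if (vec) unname(out) else out
}

#' Preprocess a trace set
#'
#' Runs the full preprocessing chain: baseline estimation, dF/F0,
#' smoothed differentiation, and baseline-fluctuation SDs of both the
#' dF/F0 signal and its derivative.
#'
#' @param traces a [trace_set()].
#' @param percentile,window_s baseline-estimation parameters, see
#'   [estimate_f0()].
#' @param smoothing_window_frames odd smoothing width before
#'   differentiation. The default of 1 (no pre-smoothing) keeps the
#'   derivative noise serially uncorrelated, which both sharpens detected
#'   onsets and makes large noise excursions of the derivative rare;
#'   wider windows trade onset accuracy for a smoother derivative.
#' @param robust use robust (MAD) baseline SDs (default `TRUE`).
#' @return Object of class `dff_traces`: list with `dff`, `deriv`
#'   (matrices), `f0`, `sigma_dff`, `sigma_deriv` (per-ROI vectors),
#'   `frame_rate_hz`, `smoothing_window_frames`, `roi_ids`.
#' @export
preprocess_traces <- function(traces, percentile = 8, window_s = 30,
                              smoothing_window_frames = 1, robust = TRUE) {
  stopifnot(inherits(traces, "trace_set"))
  window_s <- min(window_s, ncol(traces$fluorescence) / traces$frame_rate_hz)
  f0 <- estimate_f0(traces, percentile = percentile, window_s = window_s)
  dff <- compute_dff(traces, f0)
  deriv <- smooth_and_differentiate(dff, smoothing_window_frames)
  structure(list(
    dff = dff, deriv = deriv, f0 = f0,
    sigma_dff = estimate_baseline_sd(dff, robust = robust),
    sigma_deriv = estimate_baseline_sd(deriv, robust = robust),
    frame_rate_hz = traces$frame_rate_hz,
    smoothing_window_frames = as.integer(smoothing_window_frames),
    roi_ids = traces$roi_ids
  ), class = "dff_traces")
}

#' @export
print.dff_traces <- function(x, ...) {
  cat("<dff_traces>", nrow(x$dff), "ROIs x", ncol(x$dff), "frames at",
      x$frame_rate_hz, "fps\n")
  cat("  median F0:", signif(stats::median(x$f0), 4),
      " median sigma_dff:", signif(stats::median(x$sigma_dff), 3),
      " median sigma_deriv:", signif(stats::median(x$sigma_deriv), 3), "\n")
  invisible(x)
}
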