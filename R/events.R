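# Calcium-event detection.
#
# An event is the rising phase of a calcium transient. Its onset is the
# frame where the smoothed first derivative of dF/F0 crosses from <= 0 to
# > 0 and then keeps rising, exceeding k_rise baseline SDs of the
# derivative within that rising interval; the event is kept only if the
# transient peak exceeds k_peak baseline SDs of dF/F0.

#' Detector parameters
#'
#' @param k_peak SD multiplier for the peak-amplitude gate: the peak dF/F0
#'   must exceed `k_peak * sigma_dff` (default 0.5).
#' @param k_rise SD multiplier for the rise criterion: within a rising
#'   interval the derivative must exceed `k_rise * sigma_deriv`. The
#'   default of 4 is calibrated by Gaussian level-crossing statistics so
#'   that noise-only recordings yield under 0.05 false events per ROI per
#'   minute; `k_rise = 2` reproduces the threshold used for traces that
#'   have already been denoised by an extraction pipeline.
#' @param min_separation_frames refractory gap: candidates whose onset
#'   follows the previous peak by fewer than this many frames are merged
#'   (default 5 frames = 0.25 s at 20 fps).
#' @param min_rise_frames minimum number of consecutive frames the
#'   derivative must stay positive for a rising interval to count
#'   (default 3, about the rise time of a fast indicator at 20 fps).
#' @param rise_criterion which signal must exceed the `k_rise` threshold
#'   within the rising interval: the derivative of dF/F0 (`"derivative"`,
#'   default, in units of `sigma_deriv`) or dF/F0 itself (`"dff"`, in
#'   units of `sigma_dff`).
#' @return Object of class `detector_params`.
#' @export
detector_params <- function(k_peak = 0.5, k_rise = 4,
                            min_separation_frames = 5,
                            min_rise_frames = 3,
                            rise_criterion = c("derivative", "dff")) {
  check_scalar(k_peak, "k_peak", min = 0, strict_min = TRUE)
  check_scalar(k_rise, "k_rise", min = 0, strict_min = TRUE)
  check_scalar(min_separation_frames, "min_separation_frames", min = 1,
               integer = TRUE)
  check_scalar(min_rise_frames, "min_rise_frames", min = 1, integer = TRUE)
  structure(list(k_peak = k_peak, k_rise = k_rise,
                 min_separation_frames = as.integer(min_separation_frames),
                 min_rise_frames = as.integer(min_rise_frames),
                 rise_criterion = match.arg(rise_criterion)),
            class = "detector_params")
}

#' @export
print.detector_params <- function(x, ...) {
  cat("<detector_params> k_peak =", x$k_peak, " k_rise =", x$k_rise,
      "(on", x$rise_criterion, ")",
      " min_rise =", x$min_rise_frames, "frames",
      " min_separation =", x$min_separation_frames, "frames\n")
  invisible(x)
}

# Detect events in one ROI. dff/deriv are numeric vectors; frames are
# 1-based internally and reported 0-based.
detect_events_roi <- function(dff, deriv, sigma_dff, sigma_deriv, params) {
  n <- length(dff)
  pos <- deriv > 0
  if (!any(pos)) return(NULL)
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep_run <- r$values & r$lengths >= params$min_rise_frames
  onset <- integer(0); peak <- integer(0); peak_val <- numeric(0)
  for (k in which(keep_run)) {
    s <- starts[k]; e <- ends[k]
    exceeds <- if (params$rise_criterion == "derivative") {
      any(deriv[s:e] > params$k_rise * sigma_deriv)
    } else {
      any(dff[s:e] > params$k_rise * sigma_dff)
    }
    if (!exceeds) next
    # peak: first local maximum of dff at or after the end of the rise
    j <- e
    while (j < n && dff[j + 1L] > dff[j]) j <- j + 1L
    if (dff[j] <= params$k_peak * sigma_dff) next
    onset <- c(onset, s); peak <- c(peak, j); peak_val <- c(peak_val, dff[j])
  }
  if (length(onset) == 0L) return(NULL)
  # refractory merge: a candidate whose onset is closer than
  # min_separation_frames to the previous kept peak is folded into it,
  # keeping the earlier onset and the higher peak
  m_on <- onset[1]; m_pk <- peak[1]; m_val <- peak_val[1]
  out_on <- integer(0); out_pk <- integer(0); out_val <- numeric(0)
  for (i in seq_along(onset)[-1]) {
    if (onset[i] - m_pk < params$min_separation_frames) {
      if (peak_val[i] > m_val) { m_pk <- peak[i]; m_val <- peak_val[i] }
    } else {
      out_on <- c(out_on, m_on); out_pk <- c(out_pk, m_pk)
      out_val <- c(out_val, m_val)
      m_on <- onset[i]; m_pk <- peak[i]; m_val <- peak_val[i]
    }
  }
  out_on <- c(out_on, m_on); out_pk <- c(out_pk, m_pk)
  out_val <- c(out_val, m_val)
  data.frame(onset_frame = out_on - 1L, peak_frame = out_pk - 1L,
             peak_dff = out_val)
}

#' Detect calcium events
#'
#' Applies the rising-phase event definition per ROI: (1) find intervals
#' where the smoothed derivative of dF/F0 stays positive for at least
#' `min_rise_frames` frames and exceeds `k_rise` baseline SDs within the
#' interval; (2) the onset is the frame where the derivative crossed from
#' <= 0 to > 0 (frame 0 if it starts positive); (3) the peak is the first
#' local maximum of dF/F0 at or after the interval; (4) events whose peak
#' dF/F0 does not exceed `k_peak` baseline SDs are discarded; (5)
#' candidates closer than `min_separation_frames` to the previous peak are
#' merged (earlier onset, higher peak).
#'
#' @param dffset a [preprocess_traces()] result.
#' @param params a [detector_params()].
#' @return Object of class `ca_events`: a data.frame with columns
#'   `roi_id`, `onset_frame`, `onset_time_s`, `peak_frame`, `peak_time_s`,
#'   `peak_dff`, sorted by ROI then onset; attributes carry the frame
#'   rate, ROI labels, and parameters.
#' @export
detect_events <- function(dffset, params = detector_params()) {
  stopifnot(inherits(dffset, "dff_traces"))
  if (!inherits(params, "detector_params")) params <- do.call(detector_params, params)
  for (f in c("dff", "deriv", "sigma_dff", "sigma_deriv"))
    if (is.null(dffset[[f]]))
      stop_field(f, "missing from the preprocessed trace set")
  fr <- dffset$frame_rate_hz
  res <- vector("list", nrow(dffset$dff))
  for (r in seq_len(nrow(dffset$dff))) {
    dff <- dffset$dff[r, ]
    if (dffset$sigma_dff[r] == 0 && any(dff != dff[1]))
      stop("degenerate baseline SD (zero) for a non-flat trace: ",
           dffset$roi_ids[r], call. = FALSE)
    ev <- detect_events_roi(dff, dffset$deriv[r, ],
                            dffset$sigma_dff[r], dffset$sigma_deriv[r],
                            params)
    if (!is.null(ev)) {
      ev$roi_id <- dffset$roi_ids[r]
      res[[r]] <- ev
    }
  }
  res <- res[!vapply(res, is.null, logical(1))]
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(onset_frame = integer(0), peak_frame = integer(0),
               peak_dff = numeric(0), roi_id = character(0))
  out$onset_time_s <- out$onset_frame / fr
  out$peak_time_s <- out$peak_frame / fr
  out <- out[, c("roi_id", "onset_frame", "onset_time_s",
                 "peak_frame", "peak_time_s", "peak_dff")]
  rownames(out) <- NULL
  structure(out, class = c("ca_events", "data.frame"),
            frame_rate_hz = fr, roi_ids = dffset$roi_ids, params = params)
}

#' Construct an event table directly
#'
#' Wraps a bare event data.frame (e.g. read from disk or built from
#' simulated ground truth) as a `ca_events` object.
#'
#' @param df data.frame with at least `roi_id` and `onset_time_s`;
#'   missing frame/peak columns are filled from the frame rate.
#' @param frame_rate_hz frames per second.
#' @param roi_ids full ROI label set (defaults to those present in `df`).
#' @return A `ca_events` object.
#' @export
ca_events <- function(df, frame_rate_hz, roi_ids = NULL) {
  stopifnot(is.data.frame(df), all(c("roi_id", "onset_time_s") %in% names(df)))
  check_scalar(frame_rate_hz, "frame_rate_hz", min = 0, strict_min = TRUE)
  if (is.null(df$onset_frame)) df$onset_frame <- floor(df$onset_time_s * frame_rate_hz)
  if (is.null(df$peak_frame)) df$peak_frame <- df$onset_frame
  if (is.null(df$peak_time_s)) df$peak_time_s <- df$peak_frame / frame_rate_hz
  if (is.null(df$peak_dff)) df$peak_dff <- rep(NA_real_, nrow(df))
  if (is.null(roi_ids)) roi_ids <- sort(unique(as.character(df$roi_id)))
  df <- df[order(df$roi_id, df$onset_time_s),
           c("roi_id", "onset_frame", "onset_time_s",
             "peak_frame", "peak_time_s", "peak_dff")]
  rownames(df) <- NULL
  structure(df, class = c("ca_events", "data.frame"),
            frame_rate_hz = frame_rate_hz, roi_ids = roi_ids)
}

#' @export
print.ca_events <- function(x, ...) {
  cat("<ca_events>", nrow(x), "events in",
      length(unique(x$roi_id)), "of", length(attr(x, "roi_ids")),
      "ROIs\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' @export
summary.ca_events <- function(object, ...) {
  counts <- table(factor(object$roi_id, levels = attr(object, "roi_ids")))
  cat("Events per ROI: median", stats::median(counts),
      "range", min(counts), "-", max(counts), "\n")
  if (nrow(object))
    cat("Peak dF/F0: median", signif(stats::median(object$peak_dff), 3), "\n")
  invisible(counts)
}

# Greedy nearest-time one-to-one matching of two sorted time vectors.
# Returns indices of matched pairs (det, tru).
match_times_greedy <- function(det, tru, tol) {
  if (length(det) == 0L || length(tru) == 0L)
    return(list(det = integer(0), tru = integer(0), err = numeric(0)))
  pairs <- expand.grid(d = seq_along(det), t = seq_along(tru))
  pairs$dt <- abs(det[pairs$d] - tru[pairs$t])
  pairs <- pairs[pairs$dt <= tol, , drop = FALSE]
  pairs <- pairs[order(pairs$dt, pairs$t, pairs$d), , drop = FALSE]
  used_d <- logical(length(det)); used_t <- logical(length(tru))
  md <- integer(0); mt <- integer(0); err <- numeric(0)
  for (i in seq_len(nrow(pairs))) {
    d <- pairs$d[i]; t <- pairs$t[i]
    if (used_d[d] || used_t[t]) next
    used_d[d] <- TRUE; used_t[t] <- TRUE
    md <- c(md, d); mt <- c(mt, t)
    err <- c(err, det[d] - tru[t])
  }
  list(det = md, tru = mt, err = err)
}

#' Match detected events against ground truth
#'
#' Greedy nearest-time one-to-one matching of detected onsets against true
#' event times per ROI, within a time tolerance.
#'
#' @param detected a `ca_events` object (detected events).
#' @param truth a `ground_truth` object.
#' @param tolerance_s matching tolerance in seconds (>= 0).
#' @return list with `recall` (matched / true), `precision`
#'   (matched / detected; reported as 1 with `no_detections = TRUE` when
#'   nothing was detected), `n_matched`, `n_true`, `n_detected`, and
#'   `onset_errors_s` (detected minus true, matched pairs only).
#' @export
match_events <- function(detected, truth, tolerance_s = 0.25) {
  stopifnot(inherits(detected, "ca_events"), inherits(truth, "ground_truth"))
  if (tolerance_s < 0)
    stop_field("tolerance_s", "must be >= 0")
  roi_ids <- attr(detected, "roi_ids")
  if (length(roi_ids) != length(truth$event_times_s))
    stop("detected and truth must cover the same ROIs", call. = FALSE)
  n_matched <- 0L; errs <- numeric(0)
  for (r in seq_along(roi_ids)) {
    det <- detected$onset_time_s[detected$roi_id == roi_ids[r]]
    m <- match_times_greedy(det, truth$event_times_s[[r]], tolerance_s)
    n_matched <- n_matched + length(m$det)
    errs <- c(errs, m$err)
  }
  n_true <- sum(lengths(truth$event_times_s))
  n_det <- nrow(detected)
  list(
    recall = if (n_true == 0L) 1 else n_matched / n_true,
    precision = if (n_det == 0L) 1 else n_matched / n_det,
    no_detections = n_det == 0L,
    n_matched = n_matched, n_true = n_true, n_detected = n_det,
    onset_errors_s = errs
  )
}
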