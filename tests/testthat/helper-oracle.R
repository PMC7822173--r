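# Exhaustive frame-by-frame reference detector, kept deliberately naive:
# it walks the trace frame by frame, applying the event rules literally,
# and serves as the independent oracle for the vectorized detector.

oracle_detect <- function(dff, deriv, sigma_dff, sigma_deriv,
                          k_peak = 0.5, k_rise = 4,
                          min_separation_frames = 5, min_rise_frames = 3,
                          rise_criterion = "derivative") {
  n <- length(dff)
  cand <- list()
  i <- 1L
  while (i <= n) {
    if (deriv[i] > 0) {
      j <- i
      while (j < n && deriv[j + 1L] > 0) j <- j + 1L
      run_len <- j - i + 1L
      exceeded <- FALSE
      for (f in i:j) {
        v <- if (rise_criterion == "derivative")
          deriv[f] > k_rise * sigma_deriv else dff[f] > k_rise * sigma_dff
        if (v) { exceeded <- TRUE; break }
      }
      if (run_len >= min_rise_frames && exceeded) {
        p <- j
        while (p < n && dff[p + 1L] > dff[p]) p <- p + 1L
        if (dff[p] > k_peak * sigma_dff)
          cand[[length(cand) + 1L]] <-
            list(onset = i, peak = p, val = dff[p])
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(cand) == 0L)
    return(data.frame(onset_frame = integer(0), peak_frame = integer(0),
                      peak_dff = numeric(0)))
  kept <- cand[[1L]]
  out <- list()
  if (length(cand) > 1L) {
    for (k in 2:length(cand)) {
      nxt <- cand[[k]]
      if (nxt$onset - kept$peak < min_separation_frames) {
        if (nxt$val > kept$val) { kept$peak <- nxt$peak; kept$val <- nxt$val }
      } else {
        out[[length(out) + 1L]] <- kept
        kept <- nxt
      }
    }
  }
  out[[length(out) + 1L]] <- kept
  data.frame(
    onset_frame = vapply(out, function(e) e$onset, integer(1)) - 1L,
    peak_frame = vapply(out, function(e) e$peak, integer(1)) - 1L,
    peak_dff = vapply(out, function(e) e$val, numeric(1))
  )
}

# Wrap a bare dff matrix (plus precomputed stats) as a dff_traces object,
# bypassing baseline estimation — used to feed hand-built traces to the
# detector.
make_dffset <- function(dff, frame_rate_hz = 20, window = 1,
                        sigma_dff = NULL, sigma_deriv = NULL) {
  if (is.null(dim(dff))) dff <- matrix(dff, nrow = 1)
  deriv <- smooth_and_differentiate(dff, window)
  if (is.null(dim(deriv))) deriv <- matrix(deriv, nrow = 1)
  if (is.null(sigma_dff)) sigma_dff <- estimate_baseline_sd(dff)
  if (is.null(sigma_deriv)) sigma_deriv <- estimate_baseline_sd(deriv)
  structure(list(
    dff = dff, deriv = deriv,
    f0 = rep(1, nrow(dff)),
    sigma_dff = rep_len(sigma_dff, nrow(dff)),
    sigma_deriv = rep_len(sigma_deriv, nrow(dff)),
    frame_rate_hz = frame_rate_hz,
    smoothing_window_frames = as.integer(window),
    roi_ids = sprintf("roi%03d", seq_len(nrow(dff)))
  ), class = "dff_traces")
}

# Random short dff traces with occasional transient-like ramps; used for
# the detector-vs-oracle equivalence sweeps.
random_trace_case <- function(seed) {
  set.seed(seed)
  n <- sample(30:100, 1)
  x <- rnorm(n, 0, 0.02)
  for (k in seq_len(sample(0:3, 1))) {
    at <- sample(n - 10, 1)
    len <- sample(2:8, 1)
    amp <- runif(1, 0.05, 1)
    idx <- at:(at + len - 1L)
    x[idx] <- x[idx] + seq(0, amp, length.out = len)
    tail_idx <- (at + len):n
    x[tail_idx] <- x[tail_idx] + amp * exp(-(seq_along(tail_idx)) / 8)
  }
  window <- sample(c(1, 3, 5), 1)
  params <- detector_params(
    k_peak = runif(1, 0.2, 2),
    k_rise = runif(1, 1, 6),
    min_separation_frames = sample(1:8, 1),
    min_rise_frames = sample(1:5, 1),
    rise_criterion = sample(c("derivative", "dff"), 1)
  )
  list(dffset = make_dffset(x, window = window), params = params)
}
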