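test_that("a flat trace yields no events", {
  ds <- make_dffset(matrix(0, 3, 100), sigma_dff = 0.05,
                    sigma_deriv = 0.01)
  ev <- detect_events(ds)
  expect_s3_class(ev, "ca_events")
  expect_equal(nrow(ev), 0)
})

test_that("a hand-built ramp trace yields one event at the oracle-derived onset and peak", {
  # 10 flat frames, linear rise to 1.0 over 10 frames, exponential decay
  dff <- c(rep(0, 10), seq(0.1, 1.0, by = 0.1), exp(-(1:20) / 10))
  ds <- make_dffset(dff, sigma_dff = 0.05, sigma_deriv = 0.01)
  params <- detector_params(k_peak = 0.5, k_rise = 2,
                            min_separation_frames = 5, min_rise_frames = 2)
  ev <- detect_events(ds, params)
  expect_equal(nrow(ev), 1)
  # frozen from the frame-by-frame oracle: the central difference turns
  # positive one frame before the ramp's first nonzero sample
  expect_equal(ev$onset_frame, 9)
  expect_equal(ev$peak_frame, 19)
  expect_equal(ev$peak_dff, 1.0)
  o <- oracle_detect(dff, ds$deriv[1, ], 0.05, 0.01, k_peak = 0.5,
                     k_rise = 2, min_separation_frames = 5,
                     min_rise_frames = 2)
  expect_equal(ev$onset_frame, o$onset_frame)
  expect_equal(ev$peak_frame, o$peak_frame)
})

test_that("detector matches the frame-by-frame oracle on random traces", {
  for (seed in 1:200) {
    case <- random_trace_case(seed)
    p <- case$params
    ev <- detect_events(case$dffset, p)
    o <- oracle_detect(case$dffset$dff[1, ], case$dffset$deriv[1, ],
                       case$dffset$sigma_dff[1], case$dffset$sigma_deriv[1],
                       k_peak = p$k_peak, k_rise = p$k_rise,
                       min_separation_frames = p$min_separation_frames,
                       min_rise_frames = p$min_rise_frames,
                       rise_criterion = p$rise_criterion)
    expect_equal(ev$onset_frame, o$onset_frame, info = paste("seed", seed))
    expect_equal(ev$peak_frame, o$peak_frame, info = paste("seed", seed))
    expect_equal(ev$peak_dff, o$peak_dff, info = paste("seed", seed))
  }
})

test_that("detections are invariant to rescaling the raw fluorescence", {
  cfg <- sim_config(n_rois = 5, duration_s = 60, base_rate_hz = 0.05,
                    seed = 21)
  traces <- render_traces(simulate_ground_truth(cfg))
  ev1 <- detect_events(preprocess_traces(traces))
  scaled <- trace_set(traces$fluorescence * 3.7, traces$frame_rate_hz,
                      traces$roi_ids)
  ev2 <- detect_events(preprocess_traces(scaled))
  expect_equal(ev1$onset_frame, ev2$onset_frame)
  expect_equal(ev1$peak_frame, ev2$peak_frame)
  expect_equal(ev1$peak_dff, ev2$peak_dff, tolerance = 1e-9)
})

test_that("events are non-overlapping and sorted within each ROI", {
  for (s in 1:5) {
    cfg <- sim_config(n_rois = 10, duration_s = 120, base_rate_hz = 0.2,
                      seed = s)
    ev <- detect_events(preprocess_traces(render_traces(
      simulate_ground_truth(cfg))))
    for (id in unique(ev$roi_id)) {
      e <- ev[ev$roi_id == id, ]
      expect_true(all(e$onset_frame <= e$peak_frame))
      if (nrow(e) > 1)
        expect_true(all(e$onset_frame[-1] > e$peak_frame[-nrow(e)]))
    }
  }
})

test_that("detector errors on incomplete input and degenerate SDs", {
  ds <- make_dffset(rnorm(100, 0, 0.01))
  ds$sigma_deriv <- NULL
  expect_error(detect_events(ds), "sigma_deriv")
  ds2 <- make_dffset(rnorm(100, 0, 0.01), sigma_dff = 0,
                     sigma_deriv = 0.01)
  expect_error(detect_events(ds2), "degenerate")
})

test_that("perfect detection gives recall and precision 1", {
  cfg <- sim_config(n_rois = 3, duration_s = 60, base_rate_hz = 0.1,
                    seed = 31)
  truth <- simulate_ground_truth(cfg)
  det <- ground_truth_events(truth)
  m <- match_events(det, truth, tolerance_s = 0.25)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  expect_false(m$no_detections)
})

test_that("spurious extra detections reduce precision by counting", {
  cfg <- sim_config(n_rois = 1, duration_s = 200, base_rate_hz = 0,
                    network_rate_hz = 0, seed = 1)
  truth <- simulate_ground_truth(cfg)
  truth$event_times_s[[1]] <- seq(5, 95, by = 10)       # 10 true events
  det_times <- c(seq(5, 95, by = 10), seq(110, 150, by = 10)) # + 5 spurious
  det <- ca_events(data.frame(roi_id = "roi001", onset_time_s = det_times),
                   20, roi_ids = "roi001")
  m <- match_events(det, truth, tolerance_s = 0.25)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 10 / 15)
})

test_that("no detections gives zero recall and flagged unit precision", {
  cfg <- sim_config(n_rois = 2, duration_s = 60, base_rate_hz = 0.1,
                    seed = 8)
  truth <- simulate_ground_truth(cfg)
  det <- ca_events(data.frame(roi_id = character(0),
                              onset_time_s = numeric(0)),
                   20, roi_ids = sprintf("roi%03d", 1:2))
  m <- match_events(det, truth, tolerance_s = 0.25)
  expect_equal(m$recall, 0)
  expect_equal(m$precision, 1)
  expect_true(m$no_detections)
  expect_error(match_events(det, truth, tolerance_s = -1), "tolerance")
})
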