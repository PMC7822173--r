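test_that("zero-rate processes produce no events", {
  cfg <- sim_config(n_rois = 5, duration_s = 60, base_rate_hz = 0,
                    network_rate_hz = 0, seed = 7)
  truth <- simulate_ground_truth(cfg)
  expect_equal(lengths(truth$event_times_s), rep(0L, 5))
  expect_length(truth$network_times_s, 0)
})

test_that("fully shared events with no jitter equal the network stream", {
  cfg <- sim_config(n_rois = 8, duration_s = 120, base_rate_hz = 0,
                    sync_fraction = 1, jitter_s = 0,
                    network_rate_hz = 0.1, seed = 11)
  truth <- simulate_ground_truth(cfg)
  expect_gt(length(truth$network_times_s), 0)
  for (ev in truth$event_times_s)
    expect_equal(ev, truth$network_times_s)
})

test_that("event counts follow Poisson statistics across seeds", {
  n_seeds <- 200
  counts <- numeric(0)
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_rois = 20, duration_s = 120, base_rate_hz = 0.1,
                      network_rate_hz = 0, seed = s)
    counts <- c(counts, lengths(simulate_ground_truth(cfg)$event_times_s))
  }
  expected <- 0.1 * 120
  se <- sqrt(expected / length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
  # variance should also look Poisson (generous factor-level check)
  expect_gt(var(counts), expected * 0.8)
  expect_lt(var(counts), expected * 1.2)
})

test_that("simulation and rendering are bit-reproducible from (config, seed)", {
  cfg <- sim_config(n_rois = 4, duration_s = 30, sync_fraction = 0.5,
                    seed = 123)
  t1 <- simulate_ground_truth(cfg)
  t2 <- simulate_ground_truth(cfg)
  expect_identical(t1$event_times_s, t2$event_times_s)
  expect_identical(render_traces(t1)$fluorescence,
                   render_traces(t2)$fluorescence)
})

test_that("event times stay inside the recording and sorted", {
  for (s in 1:10) {
    cfg <- sim_config(n_rois = 10, duration_s = 60, sync_fraction = 0.8,
                      jitter_s = 0.5, network_rate_hz = 0.2, seed = s)
    truth <- simulate_ground_truth(cfg)
    for (ev in truth$event_times_s) {
      expect_true(all(ev >= 0 & ev < 60))
      expect_true(!is.unsorted(ev))
    }
  }
})

test_that("complete blockade thins away every post-drug event", {
  for (s in 1:20) {
    cfg <- sim_config(n_rois = 10, duration_s = 120, base_rate_hz = 0.3,
                      sync_fraction = 0.5, network_rate_hz = 0.2,
                      drug_time_s = 60, post_drug_rate_factor = 0, seed = s)
    truth <- simulate_ground_truth(cfg)
    expect_true(all(unlist(truth$event_times_s) <= 60))
  }
})

test_that("event-free noiseless rendering is a constant baseline", {
  cfg <- sim_config(n_rois = 3, duration_s = 30, base_rate_hz = 0,
                    network_rate_hz = 0, noise_sd = 0, drift_amp = 0,
                    f0_cv = 0, f0_mean = 150, seed = 5)
  traces <- render_traces(simulate_ground_truth(cfg))
  expect_true(all(abs(traces$fluorescence - 150) < 1e-9))
})

test_that("a single rendered transient peaks at the configured amplitude", {
  cfg <- sim_config(n_rois = 1, duration_s = 20, base_rate_hz = 0,
                    network_rate_hz = 0, noise_sd = 0, drift_amp = 0,
                    f0_cv = 0, amplitude = 0.8, seed = 3)
  truth <- simulate_ground_truth(cfg)
  truth$event_times_s[[1]] <- 5.0
  traces <- render_traces(truth)
  f <- traces$fluorescence[1, ]
  dff <- (f - 100) / 100
  # closed form: peak = amplitude * max of the kernel on the frame grid
  k_grid <- calcium_kernel(seq(0, 10, by = 1 / 20), 0.05, 1.0)
  expect_equal(max(dff), 0.8 * max(k_grid), tolerance = 1e-10)
  expect_equal(max(dff), 0.8, tolerance = 0.05)
  expect_true(all(dff[1:99] == 0))  # nothing before the event
})

test_that("unsynchronized ROIs are uncorrelated in 1-s bins", {
  rs <- c()
  for (s in 1:3) {
    cfg <- sim_config(n_rois = 20, duration_s = 300, base_rate_hz = 0.1,
                      sync_fraction = 0, network_rate_hz = 0.05, seed = s)
    truth <- simulate_ground_truth(cfg)
    counts <- vapply(truth$event_times_s, function(ev)
      tabulate(floor(ev) + 1L, nbins = 300), numeric(300))
    cm <- suppressWarnings(cor(counts))
    rs <- c(rs, cm[upper.tri(cm)])
  }
  expect_lt(abs(mean(rs, na.rm = TRUE)), 0.1)
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_config(sync_fraction = 1.5), "sync_fraction")
  expect_error(sim_config(frame_rate_hz = 0), "frame_rate_hz")
  expect_error(sim_config(kernel_decay_s = 0.01), "kernel_decay_s")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(drug_time_s = 500, duration_s = 300),
               "drug_time_s")
})
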