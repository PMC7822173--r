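events_at <- function(times_by_roi, n_rois, fr = 20) {
  roi_ids <- sprintf("roi%03d", seq_len(n_rois))
  df <- data.frame(
    roi_id = as.character(rep(roi_ids[seq_along(times_by_roi)],
                              lengths(times_by_roi))),
    onset_time_s = as.numeric(unlist(times_by_roi, use.names = FALSE))
  )
  ca_events(df, fr, roi_ids = roi_ids)
}

test_that("percent active follows the active-cell definition", {
  none <- events_at(list(), 50)
  expect_equal(summarize_activity(none, observation_window_s = 60)$percent_active, 0)
  some <- events_at(rep(list(10), 40), 50)
  a <- summarize_activity(some, observation_window_s = 60)
  expect_equal(a$n_active, 40)
  expect_equal(a$percent_active, 80)
  # min_events raises the bar
  two <- events_at(c(rep(list(c(5, 10)), 3), rep(list(10), 4)), 10)
  expect_equal(summarize_activity(two, observation_window_s = 60,
                                  min_events = 2)$n_active, 3)
  expect_error(summarize_activity(some, observation_window_s = 0), "window")
})

test_that("per-ROI frequencies are in events per minute", {
  ev <- events_at(list(c(10, 20, 30)), 2)
  a <- summarize_activity(ev, observation_window_s = 120)
  expect_equal(a$per_roi$freq_per_min, c(1.5, 0))
})

test_that("raster binning is half-open and exact", {
  none <- events_at(list(), 4)
  r0 <- build_raster(none, 1, 10)
  expect_equal(sum(r0$bins), 0)
  expect_equal(dim(r0$bins), c(4, 10))
  one <- events_at(list(1.5), 4)
  r1 <- build_raster(one, 1, 10)
  expect_equal(sum(r1$bins), 1)
  expect_equal(unname(r1$bins[1, 2]), 1L)  # bin [1, 2) holds t = 1.5
  expect_error(build_raster(one, 1, 1), "outside")
})

test_that("raster occupancy is bounded by event count", {
  for (s in 1:5) {
    cfg <- sim_config(n_rois = 10, duration_s = 120, base_rate_hz = 0.2,
                      seed = s)
    truth <- simulate_ground_truth(cfg)
    ev <- ground_truth_events(truth)
    r <- build_raster(ev, 1, 120)
    expect_lte(sum(r$bins), nrow(ev))
    # equality iff no two same-ROI events share a bin
    collisions <- sum(vapply(truth$event_times_s, function(t)
      sum(duplicated(floor(t))), numeric(1)))
    expect_equal(sum(r$bins), nrow(ev) - collisions)
  }
})

test_that("coactivity fractions are column means of the raster", {
  ev <- events_at(list(c(2.5), c(2.2), c(2.8), c(7.1)), 4)
  r <- build_raster(ev, 1, 10)
  co <- coactivity_histogram(r)
  expect_equal(co[3], 0.75)  # three of four ROIs in bin [2, 3)
  expect_equal(co * 4, unname(colSums(r$bins)))
  expect_true(all(co >= 0 & co <= 1))
})

test_that("maximal synchrony attains the minimal permutation p-value", {
  # every ROI fires in the same single bin
  ev <- events_at(rep(list(50.5), 20), 20)
  r <- build_raster(ev, 1, 300)
  res <- synchrony_test(r, n_shuffles = 200, seed = 4)
  expect_equal(res$sync_index, 1)
  expect_equal(res$p_value, 1 / 201)
  expect_error(synchrony_test(build_raster(events_at(list(1), 1), 1, 10)),
               "2 ROIs")
})

test_that("synchrony test is deterministic given its seed", {
  cfg <- sim_config(n_rois = 10, duration_s = 120, base_rate_hz = 0.2,
                    sync_fraction = 0.5, seed = 3)
  r <- build_raster(ground_truth_events(simulate_ground_truth(cfg)), 1, 120)
  a <- synchrony_test(r, 200, seed = 9)
  b <- synchrony_test(r, 200, seed = 9)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$null_quantiles, b$null_quantiles)
})

test_that("synchrony power increases with the shared-event fraction", {
  p_at <- function(sync, seed) {
    cfg <- sim_config(n_rois = 20, duration_s = 300, base_rate_hz = 0.1,
                      sync_fraction = sync, network_rate_hz = 0.05,
                      jitter_s = 0.1, seed = seed)
    r <- build_raster(ground_truth_events(simulate_ground_truth(cfg)),
                      1, 300)
    synchrony_test(r, 200, seed = seed)$p_value
  }
  rej <- function(sync) mean(vapply(1:12, function(s)
    p_at(sync, s), numeric(1)) <= 0.05)
  r0 <- rej(0); r4 <- rej(0.4); r8 <- rej(0.8)
  expect_lte(r0, r4)
  expect_lte(r4, r8)
  expect_gte(r8, 0.9)
})

test_that("percent active is non-decreasing in the simulated event rate", {
  pa <- function(rate, seed) {
    cfg <- sim_config(n_rois = 30, duration_s = 120, base_rate_hz = rate,
                      seed = seed)
    ev <- ground_truth_events(simulate_ground_truth(cfg))
    summarize_activity(ev, observation_window_s = 120)$percent_active
  }
  for (s in 1:5) {
    vals <- vapply(c(0.005, 0.02, 0.1, 0.5), pa, numeric(1), seed = s)
    expect_true(all(diff(vals) >= 0))
  }
})

test_that("drug modulation counts and normalizes pooled frequencies", {
  ev <- events_at(list(c(10, 20, 30, 40), c(15, 25, 70)), 2)
  d <- drug_modulation(ev, 60, pre_window = c(-60, 0),
                       post_window = c(5, 65), duration_s = 130)
  expect_equal(d$freq_pre, 6 / 1)        # 6 events in one pre minute
  expect_equal(d$freq_post, 1 / 1)       # 1 event in one post minute
  expect_equal(d$normalized_frequency, 1 / 6)
  expect_false(d$undefined)
})

test_that("degenerate and invalid drug windows are handled", {
  none <- events_at(list(), 5)
  d <- drug_modulation(none, 60, pre_window = c(-20, 0),
                       post_window = c(10, 30), duration_s = 120)
  expect_true(d$undefined)
  expect_true(is.na(d$normalized_frequency))
  ev <- events_at(list(10), 5)
  expect_error(drug_modulation(ev, 60, pre_window = c(-20, 5),
                               post_window = c(10, 30)), "pre_window")
  expect_error(drug_modulation(ev, 60, pre_window = c(-20, 0),
                               post_window = c(-5, 30)), "post_window")
  expect_error(drug_modulation(ev, 60, pre_window = c(-20, 0),
                               post_window = c(10, 30), duration_s = 80),
               "beyond")
})
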