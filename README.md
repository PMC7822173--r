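# catrace

Quantification of somatic calcium-imaging recordings from cultured
neurons — written for experiments that ask whether a population of cells
(for example, neurons induced from fibroblasts by direct reprogramming)
is functionally active: do individual cells fire, does the network fire
together, and does activity disappear under a sodium-channel blocker
such as tetrodotoxin (TTX)?

The package takes ROI-by-frame fluorescence traces (one row per cell,
acquired here at 20 frames/s), and provides:

* **ΔF/F0 preprocessing** — per-ROI baseline `F0` from a low percentile
  of overlapping windows, `ΔF/F0 = (F − F0)/F0`, a smoothed first
  derivative, and robust (MAD-based) SDs of the baseline fluctuations of
  both signals.
* **Calcium-event detection** — an event is the *rising phase* of a
  transient: its onset is the frame where the first derivative of ΔF/F0
  crosses from ≤ 0 to > 0 and stays positive while exceeding
  `k_rise · σ_deriv`; the event is kept only if the transient peak
  exceeds `k_peak · σ_dff` (defaults `k_peak = 0.5`, `k_rise = 4`; see
  the methods vignette for the calibration of `k_rise` on raw versus
  denoised traces).
* **Population statistics** — percent active cells, per-ROI event
  frequencies, binary event rasters, per-bin coactivity fractions, a
  circular-shift permutation test for network synchrony (statistic: the
  maximum coactive fraction), and pre/post-administration normalized
  frequency for pharmacology epochs.
* **A synthetic trace generator with known ground truth** — per-ROI
  Poisson event trains, an optional shared network-event stream
  (synchrony), a difference-of-exponentials indicator kernel,
  multiplicative baseline with slow drift, additive Gaussian noise, and
  an optional drug epoch that thins the post-administration event rate.
  Every detection and population statistic in the package is validated
  against this generator's ground truth.

## Worked example

```r
library(catrace)

cfg <- sim_config(n_rois = 30, duration_s = 300, base_rate_hz = 0.1,
                  sync_fraction = 0.6, network_rate_hz = 0.05, seed = 42)
truth  <- simulate_ground_truth(cfg)
traces <- render_traces(truth)
dffset <- preprocess_traces(traces)
events <- detect_events(dffset)
events
#> <ca_events> 556 events in 30 of 30 ROIs
#>   roi_id onset_frame onset_time_s peak_frame peak_time_s  peak_dff
#> 1 roi001        1205        60.25       1208       60.40 0.5047839
#> 2 roi001        1335        66.75       1338       66.90 0.5073359
#> ...

match_events(events, truth, tolerance_s = 0.25)[c("recall", "precision")]
#> $recall    [1] 0.939
#> $precision [1] 0.993

summarize_activity(events, observation_window_s = 300)
#> <activity_summary> 30 of 30 cells active ( 100.0% ) in 300 s
#>   mean frequency of active cells: 3.71 events/min

raster <- build_raster(events, bin_width_s = 1, duration_s = 300)
synchrony_test(raster, n_shuffles = 500, seed = 42)
#> <synchrony_result> sync index (max coactive fraction): 0.8
#>   null 95th percentile: 0.267  p = 0.002 ( 500 shuffles )
```

The detector recovers 94% of the simulated events with 99% precision at
±0.25 s; all 30 cells are called active; and the shared network events
produce population bursts in which up to 80% of cells are coactive in
one 1-s bin — far outside the circular-shift null (p = 0.002), so the
recording is called synchronized. `plot(raster)` draws the raster with
its coactivity histogram; `drug_modulation()` compares event frequency
before and after an administration time.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/catrace.R run-all --config run.yaml --seed 5 --out-dir out/
```

writing `traces.csv`, `events.tsv`, `roi_stats.tsv`, `activity.tsv`,
`raster.tsv`, `summary.tsv`, the resolved `config.yaml` and a log;
reruns with the same configuration and seed are byte-identical.

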