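---
title: "Detecting calcium events and network synchrony in cultured neurons"
author: "catrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting calcium events and network synchrony in cultured neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catrace)
```

## The measurement problem

Calcium imaging with a fast dye reports neuronal firing as stereotyped
fluorescence transients: a rapid rise when calcium enters the cell,
followed by a slow (~1 s) decay as the indicator unbinds. Functional
characterization of a culture — for instance, neurons induced from
fibroblasts — rests on three population readouts: the percentage of
cells that fire at all, whether cells fire *together* (network
synchrony), and whether activity is abolished by a voltage-gated
sodium-channel blocker (TTX), which demonstrates that the transients are
driven by action potentials rather than dye or motion artifacts.

`catrace` implements this quantification for ROI-by-frame trace
matrices (one averaged trace per cell, 20 frames/s by default), and
ships a synthetic generator with known ground truth so every stage can
be validated end to end.

## Signal model and preprocessing

The working signal is ΔF/F0 = (F − F0)/F0 per ROI.

* **Baseline F0.** The 8th percentile of the trace in 30-s windows with
  50% overlap, aggregated by the median across windows, giving one
  scalar per ROI. A low percentile selects quiescent frames even in
  active cells (a cell firing at 0.1 Hz with a 1-s decay spends ~90% of
  frames near baseline); the median across windows resists slow drift.
  Both knobs (`percentile`, `window_s`) are exposed; windows longer than
  the recording are an error.
* **Derivative.** An optional moving average of odd width
  `smoothing_window_frames`, then a central difference per frame,
  `d[i] = (s[i+1] − s[i−1])/2` (one-sided at the ends), in ΔF/F0 units
  per frame. The default width is **1** (no pre-smoothing) — see
  *Detector calibration* below for why.
* **Baseline-fluctuation SDs.** Detection thresholds are expressed in
  SDs of the baseline fluctuations of ΔF/F0 (`σ_dff`) and of its
  derivative (`σ_deriv`). Both are estimated robustly as
  `1.4826 × MAD` about the median, which is insensitive to sparse
  transients occupying up to ~10% of frames, so the same estimator works
  whether or not transients were excluded first; the ordinary SD is
  selectable (`robust = FALSE`) for sensitivity analysis.

## The event rule

A calcium event is the rising phase of a transient. Per ROI:

1. find maximal runs of frames where the derivative is > 0, at least
   `min_rise_frames` long, within which the derivative exceeds
   `k_rise · σ_deriv` (mode `rise_criterion = "dff"` instead requires
   ΔF/F0 to exceed `k_rise · σ_dff` within the run — the alternative
   reading of "rises above 0 and continues to increase above 2 SD",
   whose natural subject is the derivative, hence the default mode);
2. the onset is the frame where the derivative crossed from ≤ 0 to > 0
   (frame 0 if it starts positive);
3. the peak is the first local maximum of ΔF/F0 at or after the end of
   the run;
4. the event is kept only if the peak ΔF/F0 exceeds `k_peak · σ_dff`
   (default 0.5 — a deliberately permissive amplitude gate: the rise
   criterion is the effective filter, the peak gate prunes slow drifts);
5. candidates whose onset follows the previous peak by fewer than
   `min_separation_frames` (default 5 = 0.25 s) are merged, keeping the
   earlier onset and the higher peak. The merge makes events
   non-overlapping by construction; compound transients closer than the
   refractory gap are reported as one event.

All detections are scale invariant (ΔF/F0 and all thresholds are
relative), and the event count is non-increasing in both `k_peak` and
`k_rise`. A vectorized implementation is checked against an exhaustive
frame-by-frame reference on thousands of randomized traces in the test
suite.

One numerical subtlety: the central difference looks one frame ahead,
so on an idealized ramp the derivative turns positive one frame before
the first nonzero sample — onsets carry that half-frame convention
(50 ms at 20 fps), which is well inside the ±0.25 s matching tolerance
used for validation.

## Detector calibration

The two SD multipliers deserve care. For traces that have been denoised
by an extraction pipeline (background subtraction, demixing, temporal
denoising), a rise threshold of 2 SD of the residual baseline
fluctuations is conventional, and `detector_params(k_rise = 2)`
reproduces it. On *raw* noisy traces, however, a 2σ threshold on the
derivative is crossed constantly by noise alone: for a Gaussian signal,
the rate of upcrossings of a level `u·σ` scales as `exp(−u²/2)` (Rice's
formula), and at 20 fps a 2σ level is crossed several times per minute
regardless of smoothing — the threshold is relative to the very noise
that crosses it. Requiring long positive-derivative runs does not help:
smoothing lengthens the noise runs exactly as fast as it lengthens the
signal runs. To keep false calls below one per 20 ROI-minutes on
noise-only recordings, the level itself must move to ≈ 4σ, and
`k_rise = 4` is therefore the package default; the false-positive rate
at defaults is measured by the test suite and the acceptance script
(of order 0.01 events per ROI per minute).

The smoothing default of 1 (no pre-smoothing) follows from onset
accuracy. A width-`w` moving average spreads the rise backwards by
`(w−1)/2` frames, and — worse — smoothing correlates the derivative
noise, so the positive run that defines the onset is randomly extended
backwards by several frames at a rate independent of SNR. At `w = 5`
this antedates a substantial fraction of onsets by more than 0.25 s;
with `w = 1` the derivative noise is serially (slightly negatively)
correlated, backward extensions die off geometrically, and onsets land
within a frame or two of the true event. An unsmoothed derivative also
makes large excursions *rarer* (no random-walk behavior), which is what
allows `min_rise_frames = 3` — about the rise time of a fast indicator
at 20 fps — to be sufficient. Users with pre-denoised data can restore
a wider window and `k_rise = 2` together.

## Population statistics

* **Percent active.** A cell is active if it has at least `min_events`
  (default 1) detected events in the observation window; the
  denominator may be a total cell count (e.g. nuclear stain) larger
  than the number of traced ROIs.
* **Raster and coactivity.** Event onsets are binned into half-open
  1-s bins (0/1 per ROI × bin); the coactivity fraction per bin is the
  column mean. Population bursts appear as bins where a large fraction
  of ROIs are coactive.
* **Synchrony test.** The statistic is the maximum coactivity fraction;
  max is preferred over the mean because synchrony manifests as rare
  population bursts. The null preserves each ROI's event count and
  within-ROI structure while destroying cross-ROI alignment:
  independent circular time-shifts of each row, with
  `p = (1 + #{null ≥ observed})/(1 + n_shuffles)`. Its false-positive
  level on independent cultures and its power on synchronized ones are
  measured in the test suite (type-I error within Monte-Carlo bounds of
  5%; power > 0.9 at a shared-event fraction of 0.8 with 0.1 s jitter).
* **Drug modulation.** Pooled population frequency (events/min summed
  over ROIs) in a pre window and a post window relative to the
  administration time, and their ratio. Pooling matches a single
  normalized value per condition and avoids unstable per-cell ratios at
  low counts. Defaults: post window 10–30 s after administration (the
  standard observation window for an acute blocker drop-in), pre window
  the 20 s immediately before, mirroring the post window's length. A
  zero pre-window frequency flags the ratio undefined rather than
  returning infinity.

## The synthetic generator

`sim_config()` describes a recording; `simulate_ground_truth()` draws
event times; `render_traces()` turns them into fluorescence.

* Shared network events: homogeneous Poisson at `network_rate_hz`
  (default 0.05 Hz — a burst every ~20 s, typical of immature culture
  networks). Each ROI joins each burst with probability
  `sync_fraction`, jittered by `Normal(0, jitter_s)` (default 0.1 s).
* Independent events: Poisson at `base_rate_hz·(1 − sync_fraction)`
  per ROI (default base rate 0.1 Hz — a few events per minute, typical
  of spontaneously active cultured neurons).
* Drug epoch: after `drug_time_s`, events are thinned — each survives
  with probability `post_drug_rate_factor` (0 emulates complete
  blockade, 1 a vehicle control).
* Fluorescence: `F0·(1 + drift)·(1 + Σ amplitude·kernel) + noise`, with
  a difference-of-exponentials kernel `(1 − e^{−t/τ_r})·e^{−t/τ_d}`
  normalized to unit peak (τ_r = 0.05 s, τ_d = 1 s, fast-dye dynamics),
  transients superposing linearly (which keeps the closed-form peak
  oracle exact), lognormal across-ROI baselines (mean 100, CV 0.1), a
  2% sinusoidal drift with a 120-s period (the simplest confounder for
  baseline estimation), and additive Gaussian noise (SD 1 on a baseline
  of 100, i.e. σ_dff ≈ 0.01; with the default transient amplitude of
  0.5 ΔF/F0 the default SNR is ~50, and noise can be raised to probe
  the detector's SNR floor). Event times map to frames by
  `floor(t · frame_rate)`.

Everything is bit-reproducible from (config, seed): submodule RNG
streams (truth, rendering, shuffles) are derived from the single
top-level seed by a fixed Lehmer step, so adding permutation shuffles
never perturbs the simulation draws.

**What the generator does not emulate:** motion artifacts, neuropil
contamination and overlapping-ROI demixing, bleaching, indicator
saturation, and the temporally correlated, non-Gaussian residuals that
real extraction pipelines leave behind. Passing the validation suite
therefore demonstrates the correctness and calibration of the
*algorithms* under the stated noise model — not detector performance on
any particular microscope's raw data, where thresholds (notably
`k_rise`) should be revisited against the residual noise structure.

## Validation problem sizes

The test suite validates detector/oracle equivalence on 1,000
randomized short traces; event recovery on 20 recordings of 20 ROIs ×
300 s with well-separated events (base rate 0.02 Hz) at SNR 10, where
mean recall and precision exceed 0.95 at ±0.25 s; false positives on
100 noise-only recordings; synchrony type-I error on 200 independent
simulations and power on 50 synchronized ones (500 shuffles each); and
drug modulation on 120 recordings at 0.2 Hz with 60-s windows. These
sizes give stable Monte-Carlo estimates while keeping the whole suite
fast enough to run on every change.

## Degenerate inputs and conventions

Times are in seconds, frames 0-based, bins half-open `[start, end)`.
Non-positive fluorescence is rejected (F0 would be meaningless); a zero
baseline SD with a non-flat trace is a degenerate-input error, while a
genuinely flat trace simply yields no events. If no events are
detected, matching reports precision 1 with a `no_detections` flag
(zero detections are not evidence of imprecision). An event list with
no detections before an administration flags the normalized frequency
undefined. The onset tie rule: if the derivative is already positive at
frame 0, the onset is frame 0.

## Limitations

The detector reports rising phases, not spikes: no deconvolution,
amplitude-to-spike-count inference, or template matching. Compound
transients within the refractory gap merge into one event, so event
*frequency* underestimates burst spike counts. The synchrony index is a
single-bin extreme statistic: it detects population bursts but does not
quantify pairwise connectivity. Comparisons across biological
conditions (e.g. different donor ages) are left to the caller; the
package provides per-recording statistics.
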