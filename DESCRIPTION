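Package: catrace
Title: Calcium Imaging Trace Analysis for Induced Neuron Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantification pipeline for somatic calcium-imaging recordings of
    cultured neurons: conversion of ROI fluorescence traces to dF/F0 with
    robust baseline statistics, detection of calcium events as rising phases
    whose smoothed first derivative crosses zero and exceeds a
    baseline-noise threshold, population activity summaries (percent active
    cells, event rasters, coactivity histograms), a circular-shift
    permutation test for network synchrony, and pre/post-administration
    frequency analysis for pharmacological blockade experiments. Includes a
    synthetic fluorescence-trace generator with known ground truth (Poisson
    event trains, shared network events, indicator-kernel convolution,
    baseline drift and noise, optional drug epoch) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
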