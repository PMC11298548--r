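# gliaxon

Analysis toolkit for two-photon imaging studies that relate motor-cortex
layer-5 population activity to spinal-cord microglia–axon interaction —
the quantitative setting of spinal cord injury (SCI) and transcranial
direct current stimulation (tDCS) experiments, where the readouts are
neuronal synchrony in the cortex and microglial behaviour near the
injured pyramidal tract.

It is written for imaging labs that have ROI fluorescence traces,
registered two-channel time-lapse stacks (microglia + axons), and
process-tip tracks, and want the downstream numbers computed reproducibly:

* **Calcium analytics** — baseline `F0` as the 35th percentile of the
  intensity histogram; `ΔF/F0 = (F − F0)/F0`; transients as excursions
  exceeding 2 noise SDs (with hysteresis and debouncing); per-event power
  `p_x = (1/T) Σ x_i²`; frequency; pairwise synchrony by the non-centred
  cosine correlation
  `r_c = Σ x_i y_i / (√Σ x_i² · √Σ y_i²)`
  (Pearson's `r_p` available for comparison), and session means
  standardized to a pre-session.
* **Morphometry** — temporal-SD projection, soma extraction by the
  half-maximum wand rule (8-connected growth to half the seed intensity,
  exclusion of merged and border-touching regions), equivalent-ellipse
  metrics (area, aspect ratio, circularity `4πA/P²`, roundness
  `4A/(π·major²)`), and cell density per field / per mm².
* **Interaction** — per-channel Otsu binarization (256-bin histogram over
  the observed range), colocalization ratio = merged area / axon area,
  process moving vectors (farthest in-window point from the start), axial
  angle folding into [0°, 90°], and empirical angle CDFs.
* **Circular statistics** — the Mardia–Watson–Wheeler uniform-scores test
  `W = 2 Σ_j (C_j² + S_j²)/n_j` with asymptotic `χ²_{2(k−1)}`,
  permutation, and exact small-sample modes.
* **Synthetic data** — seeded generators for correlated calcium traces
  (shared vs private event trains), two-channel stacks with controllable
  soma ellipticity, von Mises process orientations and a calibrated
  microglia-over-axon overlap fraction, tip trajectories, and grouped
  angle samples — each emitting ground truth for parameter-recovery
  testing.

The methods vignette (`vignettes/gliaxon-methods.Rmd`) documents every
model assumption, parameter default, and numerical convention.

## Worked example

Simulate six ROIs whose activity is 75% driven by shared population
events, then run the calcium chain:

```r
library(gliaxon)

sim <- simulate_traces(trace_sim_config(n_rois = 6, shared_rate = 0.03,
                                        private_rate = 0.01, seed = 42))
tr  <- sim$traces[[1]]
f0  <- compute_baseline(tr)          # 35th-percentile baseline
dff <- compute_dff(tr, f0)
ev  <- detect_transients(dff, min_duration_frames = 3)
head(ev, 3)
#>   onset_frame offset_frame      peak     power
#> 1          28           49 0.9067373 0.2379343
#> 2         116          129 1.1967613 0.4329322
#> 3         154          177 1.4990491 0.7207488

transient_frequency(ev, length(tr$values) * tr$frame_interval)
#> [1] 0.05734767

dffs <- lapply(sim$traces, function(t) compute_dff(t, compute_baseline(t)))
pairwise_synchrony(dffs)
#> <synchrony_matrix (cosine): 6 ROIs, mean pairwise r = 0.6289, 0 undefined pair(s)>

standardize_to_pre(c(Pre = 0.6289, POD2 = 0.21, POD7 = 0.33))
#>   session mean_r standardized
#> 1     Pre 0.6289    1.0000000
#> 2    POD2 0.2100    0.3339164
#> 3    POD7 0.3300    0.5247257
```

Each detected event row gives the frame bounds of one transient, its peak
ΔF/F₀ and its mean-squared-amplitude power. The mean pairwise cosine
correlation (0.63 here) reflects the high shared-event fraction of the
simulation, and the standardized table expresses post-operative sessions
relative to the pre-operative level (Pre ≡ 1).

The stack side is one call each:

```r
st   <- simulate_stack(stack_sim_config(seed = 1))
proj <- sd_projection(st$stack, channel = 1)
regs <- extract_cell_bodies(proj, seed_min_intensity =
                              (median(proj$pixels) + max(proj$pixels)) / 2)
morphometry_summary(regs, proj$pixel_size_um, field_size_um = 264.9)
```

`run_pipeline("all", run_config(seed = 1), "out/")` chains every stage on
a self-generated dataset and writes CSV tables plus a provenance-carrying
`report.json`; `exec/gliaxon` exposes the same subcommands
(`simulate | calcium | morpho | coloc | polarity | mww | all`) from a
shell.

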