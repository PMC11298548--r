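---
title: "Methods: calcium synchrony and microglia-axon interaction analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium synchrony and microglia-axon interaction analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliaxon)
```

# Scope

`gliaxon` implements the quantitative arm of a two-photon imaging workflow
that relates layer-5 motor-cortex population activity to spinal-cord
microglia--axon interaction: calcium transient detection and pairwise
synchrony on ROI traces, microglial soma morphometry on time-lapse stacks,
microglia--axon colocalization, process-polarity angles, and the
Mardia--Watson--Wheeler (MWW) test for circular samples. Wet-lab stages,
ROI segmentation, image registration, and manual tip tracking are outside
the package: traces, registered stacks and tip tracks are inputs. Seeded
generators produce all three input kinds with known ground truth, so every
stage can be validated by parameter recovery rather than by eye.

# Calcium trace analytics

## Baseline, ΔF/F₀ and the noise scale

The baseline $F_0$ is the 35th percentile of the intensity histogram of the
whole recording, computed with linear interpolation between order
statistics (`stats::quantile` type 7). The percentile convention matters at
small frame counts, so it is pinned by tests against an independently coded
interpolation oracle. Activity is expressed as $\Delta F/F_0 = (F - F_0)/F_0$.

Thresholding "two standard deviations of the baseline fluorescence"
requires a noise SD that transients themselves do not inflate. The default
estimator takes the SD of the below-median residuals of $\Delta F/F_0$ --
transients live in the upper tail, so the lower half is noise-dominated --
and rescales by the half-normal consistency factor $1/\sqrt{1-2/\pi}$ so
that the result estimates the *full* Gaussian noise SD rather than the
SD of a half distribution (about 0.60 of it). A median-absolute-deviation
estimator and the plain full-trace SD are available via
`compute_dff(estimator=)` for sensitivity analyses.

## Transient detection

A transient is an excursion above `offset_multiplier` (default 0.5) noise
SDs that contains at least `min_duration_frames` frames above the detection
threshold of `sd_multiplier` (default 2) noise SDs; both thresholds are
centred on the trace median of $\Delta F/F_0$. Three small decisions keep
single-threshold run detection from misbehaving on realistic traces:

* **Median centring.** The 35th-percentile baseline deliberately sits below
  the noise median, so $\Delta F/F_0$ is slightly positive at rest. A
  threshold anchored at zero would therefore sit closer to the noise than
  its nominal multiplier suggests; centring on the median restores the
  intended distance.
* **Hysteresis.** A decaying transient hovers around any single threshold
  and would fragment into several counted events. The low offset threshold
  keeps the event open through the decay; the high threshold still decides
  detection. Setting `offset_multiplier = sd_multiplier` recovers the plain
  runs-above-threshold rule.
* **Debouncing.** Sub-threshold dips of at most `bridge_frames` (default 2)
  frames inside an excursion are bridged, so one noisy frame cannot split
  an event whose tail is still clearly suprathreshold.

Onsets are reported at the first detection-threshold crossing, offsets at
the excursion end (half-open frame interval). Each event carries its peak
and its power $p_x = \frac{1}{T}\sum_{i=1}^{T}x_i^2$, the mean squared
amplitude over the event. Frequency is the event count divided by the
session duration in seconds.

## Synchrony

Pairwise co-activity uses the non-centred cosine correlation
$r_c = \sum_i x_i y_i / (\sqrt{\sum_i x_i^2}\sqrt{\sum_i y_i^2})$ rather
than Pearson's $r_p$: centring turns long shared silences into agreement
and inflates $r_p$ for sparsely active pairs, whereas $r_c$ is near zero
unless both neurons are active together. Both are exposed; for mean-zero
inputs they coincide, which is tested to machine precision. Pairs with a
zero-norm (or constant, for $r_p$) member are recorded as undefined,
excluded from the mean, and counted -- never imputed. Session means are
standardized as a ratio to the pre-session mean (the pre-session maps to 1
by construction); a difference mode exists as a flag.

# Morphometry

Stacks are collapsed by a temporal standard-deviation projection
(population SD, divisor $N$). Soma extraction re-creates the ImageJ wand
rule with tolerance at half the maximum-intensity point: every accepted
seed -- an automatically detected local maximum at or above
`seed_min_intensity`, or a manually supplied point -- grows into the
8-connected region of pixels at or above *half the seed intensity*. "Half
of the seed" is the default reading; a midpoint variant
(`halfmax = "midpoint"`, halfway between seed and median background) is
available. Two automatic-seeding details: connected plateaus of equal
maxima collapse to a single representative (a uniform disc is one peak,
not hundreds), and surviving peaks closer than `min_seed_separation_px`
(default 30 px, about one soma diameter at the default pixel size) are
treated as duplicate peaks of one cell. Regions containing more than one
accepted seed are excluded as indistinguishable from an adjacent cell, and
regions touching the field border are excluded because truncated shapes
bias the ellipse fit.

Shape metrics come from the equivalent ellipse of the second-order central
moments of the pixel set: aspect ratio (major/minor), roundness
$4A/(\pi\,\mathrm{major}^2)$, area in µm² via the pixel size, and
circularity $4\pi A/P^2$. The perimeter $P$ uses the Freeman chain code of
the Moore-traced boundary with Kulpa's corrected weights (0.948 per axis
move, 1.340 per diagonal move). Plain $1/\sqrt{2}$ chain weights
overestimate a digitized disc's perimeter by roughly 4%, pushing its
circularity to about 0.94; the Kulpa correction brings digitized discs to
circularity ≈ 1 (values are clamped at 1, since corrected digitized
perimeters can slightly undershoot). Density is the included-region count
per field, also converted to cells/mm².

# Colocalization and polarity

Each channel's SD projection is binarized by Otsu's method on a 256-bin
histogram spanning the observed min--max range (so 16-bit or float inputs
need no prior rescaling; ImageJ's 8-bit convention is the special case).
Pixels strictly above the threshold are foreground. The colocalization
ratio is the pixelwise-AND area divided by the axon foreground area.
Otsu's criterion is a *global bimodal* split: when one channel mixes two
foreground brightness classes that together cover only a few percent of
the field, maximizing between-class variance can legitimately cut between
the two foreground classes instead of between background and foreground.
This is a property of the method (shared with the ImageJ implementation),
so colocalization validation uses uniform-brightness microglia rendering;
mixed-brightness channels remain a documented limitation.

Process polarity takes each tip track, restricts it to the analysis window
(default 60 min), and defines the moving vector from the first position to
the in-window position farthest from it (earliest on ties). Its angle --
image convention, +x rightward, +y downward, counter-clockwise degrees --
is folded against the axon axis (the chord between the two visible
endpoints, an axial quantity modulo 180°) into $[0^\circ, 90^\circ]$ via
$d = |\theta_1-\theta_2| \bmod 180$, then $180-d$ if $d>90$. Tips that
never leave their start have undefined polarity and are excluded rather
than assigned 0°, which would bias the distribution toward alignment.
Folded samples are summarized as right-continuous empirical CDFs.

# The Mardia-Watson-Wheeler test

Pooled angles are replaced by circular ranks $\beta_i = 2\pi R_i/N$
(average ranks on ties, with a warning above 10% ties); with group
resultants $C_j, S_j$ the statistic is $W = 2\sum_j (C_j^2+S_j^2)/n_j$,
asymptotically $\chi^2_{2(k-1)}$. Folded $[0,90]$ samples are mapped onto
the circle by multiplying by 4 before ranking; the map is monotone, so $W$
is identical to ranking raw folded values (`fold_scale = 1` exists for
clarity, not effect). `method = "auto"` switches to label permutation when
any group has fewer than 10 observations; permutation p-values use the
add-one correction and a caller-supplied seed; for two tiny groups,
`method = "exact"` enumerates all label assignments. Monte-Carlo
calibration (2000 uniform null replicates at $n_j = 30$) and
asymptotic-versus-permutation agreement are exercised by the test suite
and the acceptance script.

# What the generators emulate -- and what they do not

**Traces.** Each ROI is
$F(t) = F_b\,(1 + \sum_e a\,e^{-(t-t_e)/\tau} + \varepsilon)$: shared
events (identical times in all ROIs) and private events drive an
instantaneous-rise, single-exponential kernel; noise is additive Gaussian.
The synchrony fraction $s =$ shared/(shared+private) is the ground-truth
dial for synchrony recovery. Event trains are renewal processes whose mean
interval is exactly $1/\mathrm{rate}$; `min_event_gap` adds a dead time
without biasing the rate, keeping events resolvable where the validation
question is detection fidelity rather than deconvolution of overlapping
events (threshold detection cannot split merged excursions -- a real
limitation, not hidden by the tests). Defaults describe the emulated
session: 558 frames at 0.25 s, event amplitude 1 ΔF/F₀, τ = 2.5 s
(a population-burst scale rather than a single-spike indicator kernel),
noise SD 0.2 (SNR 5), baseline 100 a.u. The recordings being emulated
publish no SNR or event rates, so these are explicit free parameters of
the study conditions, chosen once from a power analysis of the detector
and documented here, not claims about the original data.

**Stacks.** A 264.90 µm field at 512 × 512 px (0.517 µm/px), 90 frames at
2 min. Channel 2 holds parallel axon bands at a common orientation;
channel 1 holds elliptical somas (default 12 × 7 µm) with straight
processes whose directions are von Mises around the axon orientation with
concentration κ. The microglia-over-axon overlap is calibrated to
`overlap_fraction_target` by adding or carving process pixels along the
axons, so ground truth equals the target up to pixelation. Per-pixel
Gaussian noise is set by `snr`; each frame also carries a per-channel
multiplicative brightness modulation (`fluct_sd`, default 0.3) so the
temporal-SD projection of these otherwise static scenes has structural
contrast -- in vivo, motile processes supply that temporal variance, and
full motility simulation is out of scope. Processes render at 0.35 of soma
intensity by default, safely below the half-maximum growth cut; setting
`process_intensity = soma_intensity` produces the cleanly bimodal channel
used for colocalization validation. Not emulated: optical PSF, motion
artifacts, 3-D volumes (frames are 2-D projections), process tortuosity.
Recovery tests on these scenes therefore demonstrate correctness of the
measurement chain, not robustness to every in vivo nuisance.

**Tracks and angles.** Tips drift outward along their process direction at
`tip_speed` (0.1 µm/min) with isotropic Gaussian jitter (0.3 µm) sampled
every 2 min; over a 60-min window the ~6 µm drift dominates the jitter, so
moving-vector angles recover process directions to a few degrees. Grouped
von Mises angle samples (Best--Fisher sampler, written here because no
circular-statistics package is available in the target environment) feed
MWW calibration; κ = 0 reduces to the circular uniform.

# Validation problem sizes

The acceptance experiments use: synchrony -- 10 ROIs × 558 frames, total
event rate 0.05 /s, 20 replicate seeds per $s \in \{0, .25, .5, .75, 1\}$;
detection at SNR 5 -- count fidelity on 20 single-ROI sessions at
0.02 events/s with an 8 s dead time and a 4-frame duration gate, rate
recovery pooled over 20 × 10 sessions at 0.03 events/s with a 3-frame
gate (the two gates reflect the two questions: per-event certainty versus
unbiased rates); morphometry -- digitized semi-axes 20/10 px and 20/20 px
reference shapes plus six-soma stacks at SNR 10; colocalization -- 256 px
stacks, 60 frames, target 0.25, SNR 10; MWW -- 2000 null replicates at
$n_j=30$, exact enumeration at $n_j=3$, 200 × 4999 permutations at
$n_j=50$; polarity -- κ = 20 (aligned, 60 processes) and κ = 0 (uniform,
500 processes). These sizes make each recovery property decisively
testable while keeping the whole suite runnable in about a minute.

# Known limitations

* Threshold detection counts suprathreshold excursions; events closer than
  the decay resolution merge, and amplitudes below ~2 noise SDs are
  invisible. No deconvolution is attempted.
* Otsu binarization assumes an approximately bimodal histogram per channel
  (see above).
* The wand rule assumes somas are the brightest structures in their
  neighbourhood; heavily overlapping cells are excluded, not split.
* The MWW asymptotic null degrades under heavy ties (folded angle data
  quantized to few distinct values); the permutation path is recommended
  there and chosen automatically for small groups.
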