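---
title: "Functional mapping of islet Ca2+ dynamics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional mapping of islet Ca2+ dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

Pancreatic islets respond to glucose with coordinated, quasi-periodic Ca2+
oscillations across their beta-cell population. A minority of
"hub" beta cells — typically a few percent of the population, often with an
immature transcription-factor profile (PDX1^LOW^) — are disproportionately
co-active with the rest of the islet and are thought to coordinate these
responses. `isletmap` implements the analysis chain used to map this
organisation from time-lapse recordings:

1. **Trace normalization** — F/F~min~ for single-dye indicators, channel
   ratios (340/385 nm for Fura2, Cerulean/Citrine for Epac probes).
2. **Denoising and detrending** by empirical mode decomposition (EMD).
3. **Binarization** of each cell's activity with a 20% dynamic-range
   threshold.
4. **Co-activity network inference**: the pairwise statistic
   $C_{ij} = T_{ij} / \sqrt{T_i T_j}$ with a permutation null, hub
   classification from the fraction of correlated links, and connectivity
   maps over the ROI coordinates.
5. **Wavelet analysis**: bias-corrected continuous Morlet spectra for
   time-localized oscillation frequency.
6. **Immunofluorescence quantification**: per-cell stain intensities,
   normalized LOW/HIGH maturity distributions, CTCF, and 2^−ΔΔCt^ fold
   changes.

Because no public imaging dataset accompanies this analysis style, the
package ships a synthetic-islet generator with planted network structure,
so that every stage can be exercised against a known ground truth.

# The synthetic islet

`generate_islet_traces()` simulates a monolayer of coupled bursting cells.

**State model.** Each cell is a discrete-time two-state (quiescent /
bursting) Markov chain whose dwell times are Erlang-shaped: the observable
state is traversed through `dwell_shape = 16` internal substages, giving
dwell-time coefficients of variation of $1/\sqrt{16} = 0.25$. This choice is
deliberate: glucose-stimulated islet Ca2+ oscillations are quasi-regular,
not memoryless. A memoryless (exponential-dwell) telegraph process scatters
its spectral content so broadly that EMD-based detrending cannot separate
activity from baseline — in our tests, binarization agreement with the
true state collapsed to 0.55–0.80 for exponential dwells versus ≈ 0.95 for
the staged model. The defaults (mean burst 1.5 s, mean quiescence 12 s at
full drive, 20 Hz sampling) give fast oscillations in the range seen during
sustained stimulation.

**Drive and protocol.** A `stim_protocol()` table assigns each epoch a
drive level in [0, 1] that scales the onset rate: a low-glucose baseline
(drive 0.1) is mostly silent, stimulatory glucose (drive 0.8) produces
sustained oscillation, `kcl` forces every cell ON (depolarisation), and
`silenced` multiplies the onset probability by the epoch drive (partial
chemogenetic suppression).

**Hubs.** A `hub_fraction` of cells (default 10%) is planted as hubs,
placed by farthest-point sampling so their follower territories tile the
islet. Hubs differ from ordinary cells in three ways, mirroring their
description as highly connected coordinating cells: (i) they are wired to
`hub_degree_fraction = 0.35` of the population (ordinary cells get
`k_neighbors = 3` spatial neighbours); (ii) their influence weight is
`hub_weight_boost = 10` — influence is scaled so a single bursting hub
saturates a follower's coupling drive, while an ordinary neighbour
contributes only 1/10; and (iii) their bursts are longer
(`hub_burst_boost = 6`, ≈ 9 s) and slightly more frequent
(`hub_drive_boost = 1.2`), so hub activity spans the shorter bursts of the
cells it recruits. The coupling gain `coupling_strength = 0.12` is the
package's reference coupling: it was calibrated once, during generator
design, as the operating point where hub recruitment is strong enough for
recovery but weak enough that the islet does not phase-lock globally
(global synchrony makes every pair significant and erases the hub/non-hub
degree contrast).

**Fluorescence rendering.** The binary state is convolved with a 0.2 s
exponential kernel (indicator on/off kinetics), scaled by a per-cell
amplitude, and added to a per-cell baseline with slow sinusoidal drift
(`drift_amplitude = 0.1`, one cycle per recording) plus Gaussian noise
(`noise_sd = 0.05` of the burst amplitude — realistic for 20 Hz islet
recordings, where transients are large relative to shot noise). The
un-smoothed binary state is returned as the ground-truth raster.

**What the generator does not emulate.** Electrophysiological detail
(no channel or metabolic modelling), paracrine signalling, 3-D geometry,
motion, bleaching, and cell-segmentation error. Passing the recovery tests
therefore shows that the analysis chain is correct and well calibrated on
data matching its assumptions — not that it is robust to every artefact of
real recordings.

# Trace processing

**F~min~ rule.** F/F~min~ uses the 5th percentile of the baseline epoch
(whole trace if no baseline), which approximates the minimum fluorescence
while resisting single-frame dropouts. Non-positive F~min~ is an error
naming the offending cells.

**EMD.** `emd_decompose()` implements classical sifting: cubic-spline
envelopes through local extrema (two extrema mirrored beyond each
boundary), a Cauchy-type stopping criterion (relative change < 0.2, at most
50 sifts per IMF, at most 12 IMFs), extraction until the remainder is
monotone. Because each IMF is an exact difference of intermediate
remainders, IMFs + residue always reconstruct the input to machine
precision; the test suite enforces < 1e-8 relative error.

**Component selection.** `detrend_denoise()` reconstructs each trace from
its intermediate IMFs. Noise is defined as the leading IMFs whose mean
period (from the zero-crossing rate) is below `noise_period_s = 0.5` s —
no Ca2+ burst is faster than that, so those components can only be
measurement noise. We deliberately do not hard-code "drop IMF 1": on a
noiseless signal the first IMF *is* the signal, and a single-IMF rule also
leaves roughly half of any white-noise energy (noise energy halves from
each IMF to the next) in the trace. Trend is the residue plus IMFs with
mean period above half the record. Cells yielding fewer than two IMFs pass
through with only the residue removed, and are logged.

**Binarization.** A cell is ON where its signal exceeds its robust minimum
(1st percentile) by more than `threshold_fraction = 0.20` of its robust
dynamic range (1st to 99th percentile). Percentile extrema resist residual
spikes; on a noiseless square wave the ON fraction equals the duty cycle
exactly for any threshold strictly between trough and crest. A cell with
zero dynamic range is all-OFF.

One practical caveat, visible in the pipeline design: the threshold is a
*global* per-cell quantity. If a recording is one-third silent baseline,
the detrended baseline segment sits mid-range and a global 20% cut marks it
ON. The pipeline therefore binarizes and assesses co-activity within the
stimulation window (configurable via the connectivity block's `window`),
matching the practice of measuring beta-cell connectivity during
stimulation.

**Response metrics.** Amplitude is the mean normalized signal during the
stimulus minus the baseline mean, computed on the *normalized* traces
(detrending would remove exactly the offset being measured). A cell is
responsive when its amplitude exceeds `k_sd = 2` baseline standard
deviations (a conventional criterion; exposed as configuration). Pulse
duration is the mean length of contiguous ON runs of the binary raster
during the stimulus — an interpretation consistent with the binarized
framework rather than a width-at-half-maximum of raw pulses — and
oscillation frequency is the ON-run onset count per second of stimulus.

# Co-activity and hubs

`coactivity_matrix()` computes $C_{ij} = T_{ij}/\sqrt{T_i T_j}$ from the
ON-frame counts. Cells never ON are flagged inactive, get $C = 0$ and
$p = 1$, and are excluded from the denominators of hub fraction and
percent-connected-pairs.

**Permutation null.** Each cell's row is randomized independently and the
statistic recomputed; the default scheme is an independent random circular
shift per row, which preserves each cell's burst-length autocorrelation
while destroying cross-cell alignment. (Full shuffling is available but
inflates significance for bursty traces, since it destroys within-cell
burst structure too.) Because $T_i$ is shift-invariant, null and observed
$T_{ij}$ are compared directly as integers. The p-value uses the add-one
estimator $p = (1 + \#\{C^{null} \ge C^{obs}\})/(1 + N)$ with $N = 1000$
permutations and $\alpha = 0.05$ by default; no multiple-testing correction
is applied by default (Benjamini–Hochberg is available).

**Hub rule.** Hubs hold 60–100% of the correlated links. The normalizer is
ambiguous in common usage; the default reads it as a percentage of the
maximum per-cell link count in the same islet, because hubs are only a few
percent of cells and a cell linked to 60% of *all* others is rarely
attainable. The alternative reading (percent of $n-1$ possible partners) is
available via `normalization = "n_minus_1"`. Ties at the threshold are
included; a fully connected graph classifies every cell as a hub (a
documented degenerate case).

**Reference recovery condition.** The planted-hub recovery checks run 20
simulated islets (50 cells, 10% hubs, reference coupling, 360 s of
sustained glucose at 20 Hz, N = 1000, α = 0.05). At this operating point
the pipeline recovers hubs with mean sensitivity ≈ 0.88 and specificity
≈ 0.98, a recovered hub fraction of ≈ 0.11, and per-frame raster agreement
≈ 0.92 — the test suite asserts ≥ 0.8, ≥ 0.9, [0.01, 0.15] and ≥ 0.9
respectively.

# Wavelet analysis

`morlet_cwt()` is a continuous Morlet transform (ω₀ = 6) over dyadic
scales $s_j = 2\,dt \cdot 2^{j/12}$ up to half the record, computed by FFT
convolution with zero-padding to the next power of two (padding removed
before output). Power is reported as $|W|^2/s$: dividing by scale removes
the systematic inflation of spectral power with period, so equal-amplitude
oscillations at 5 s and 20 s show equal peak power (within 10% in the test
suite; uncorrected they differ severalfold). The cone of influence is the
e-folding time $\sqrt{2}s$ expressed as a period; `dominant_period()`
excludes periods beyond the local COI and summarises a window by the
median dominant period. Spectra from several cells are averaged
arithmetically on the common period grid ("mean wave").

# Stain quantification

`measure_cells()` follows the ImageJ-style recipe: Gaussian filter
(σ = 2 px), Otsu auto-threshold, binarization to a mask, connected
components with optional distance-transform watershed splitting (on by
default; real nuclei touch even though the synthetic fixture avoids it),
and a 20 px minimum area. Mean intensity is always measured on the
original, unfiltered image.

One measurement choice deserves emphasis: with a single global threshold,
the mask area of a dim nucleus ends much smaller (and hence its masked
mean much closer to its peak) than that of a bright nucleus — the measured
mean would depend on where the global cut happens to slice each intensity
profile. By default each component's measurement region is therefore
refined to the pixels above the component's half-maximum over the
background estimate, making the reported mean a consistent, per-cell
quantity (`refine = "mask"` restores the plain masked mean). The synthetic
generator records the analytic mean over the half-maximum disc as each
cell's ground truth, and the tests require measured means within 10% of
it.

**Distributions and maturity.** Per-cell intensities are mapped to a 0–100
scale — by default the pooled 1st/99th percentiles map linearly to 0/100
with clipping; per-image min–max and normalize-to-reference (e.g. DAPI)
variants are selectable — and binned into 21 half-open width-5 bins
[0, 5), …, [100, 105). The half-open convention makes the 15-unit maturity
cutoff exactly the bottom three bins, and a cell at exactly 15.0 is HIGH.
Whether normalization should pool per islet, per animal or per batch is
left to the caller (the `intensities` argument accepts any pooling).

Note one property of percentile-anchored normalization: because the pooled
1st percentile maps to 0 by construction, even a purely unimodal (all-HIGH)
sample leaves its left tail — around 5–8% of cells — below 15 normalized
units. The LOW fraction is therefore meaningful as a *contrast* against a
bimodal distribution, not as an absolute zero-background count; an
absolute-intensity anchor would remove this tail but make the 15-unit
cutoff depend on overall staining brightness.

**Synthetic stain images.** Nuclei are Gaussian spots (σ = 5 px) placed
with ≥ 4σ separation over a constant background, with peak intensities
from a LOW/HIGH mixture (defaults 7000/15000, i.e. LOW ≈ 45% of HIGH —
"low" transcription-factor cells are dim, not negative). The LOW component
is kept clearly above background because a global Otsu threshold on a
mostly-background image with two foreground brightness classes drifts
between the foreground modes; nuclei dimmer than that cut cannot be
segmented by any Otsu-based routine, synthetic or real.

**CTCF** is the exact identity
`integrated_density − roi_area × background_mean` (negative values are
legitimate and flagged), and `fold_change_ddct()` is the exact 2^−ΔΔCt^
computation.

# Pipeline and reproducibility

`run_islet_pipeline()` chains simulate → process → connect → spectral →
quantify, writing per-stage CSV artifacts, PNG figures, a `summary.json`
and a run log. A single global seed fans out to per-stage seeds through a
fixed affine counter derivation, so any stage can be re-run independently
yet deterministically; two runs with the same configuration are
byte-identical in their CSV/JSON outputs. Floating-point CSV output is
written at 9 significant digits. The problem sizes used by the shipped
checks (50-cell islets, 300–360 s recordings, 1000 permutations, 20
recovery seeds, 256×256 stain images) were chosen as the smallest at which
the Monte-Carlo margins above are stable.

A worked end-to-end example:

```{r, eval = FALSE}
library(isletmap)
cfg <- islet_pipeline_config(seed = 42)
res <- run_islet_pipeline(cfg, outdir = "islet_run")
res$summary
```

# Known limitations

* EMD-based detrending assumes oscillatory activity; sparse, irregular
  spiking (exponential dwell times) defeats the global 20% threshold, as
  does a long silent baseline included in the thresholded window.
* The permutation null preserves autocorrelation but not slow
  nonstationarity; a drifting ON rate shared across cells can inflate
  significance.
* The hub rule's relative (percent-of-maximum) normalization makes hub
  calls sensitive to the single best-connected cell in small islets.
* Otsu thresholding requires the dimmest nuclei to be separated from
  background after Gaussian filtering; very dim subpopulations need a
  different `threshold_method`.
* The wavelet implementation reports no significance contours against a
  noise background; peaks should be read comparatively, not as hypothesis
  tests.
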