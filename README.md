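# isletmap

Functional mapping of pancreatic islet Ca²⁺ dynamics and β-cell maturity
from imaging data.

Islets respond to glucose with coordinated Ca²⁺ oscillations across their
β-cell population, and a small subpopulation of highly connected "hub"
cells — often carrying an immature PDX1^LOW/MAFA^LOW profile — appears to
coordinate these responses. `isletmap` is for researchers who record
multicellular Ca²⁺ movies (Fluo8/GCaMP/Fura2) and stain islets for maturity
markers, and want a reproducible, tested version of the full mapping chain:

* **Trace processing** — F/F_min and ratiometric (340/385,
  Cerulean/Citrine) normalization; denoising/detrending by empirical mode
  decomposition (Hilbert–Huang sifting); activity binarization at a 20%
  dynamic-range threshold; per-cell response metrics (amplitude, pulse
  duration, % responsive cells, oscillation frequency).
* **Connectivity** — for every cell pair, the co-activity coefficient

  $$C_{ij} = \frac{T_{ij}}{\sqrt{T_i\,T_j}}$$

  where `T_i`, `T_j` are the frames each cell spends ON and `T_ij` the
  frames both are ON together; per-pair significance against a circular-
  shift permutation null; hub classification (cells holding 60–100% of the
  correlated links); connectivity maps over ROI coordinates.
* **Spectra** — bias-corrected continuous Morlet wavelet transforms
  (power = |W|²/scale, so power is not compressed as period lengthens),
  cone of influence, time-localized dominant period.
* **Stain quantification** — Gaussian filter + Otsu segmentation, per-cell
  mean intensities, normalized 0–100 frequency distributions in width-5
  bins, LOW/HIGH maturity split at 15 normalized units, corrected total
  cell fluorescence (CTCF), and 2^−ΔΔCt fold changes.
* **Synthetic data** — a seeded islet simulator (coupled Erlang-staged
  bursters with planted hubs on a spatial graph) and a nuclei-stain image
  generator with a planted LOW/HIGH mixture, so the whole chain is testable
  against known ground truth.

## Worked example

Simulate an islet, map its network, and quantify a synthetic stain:

```r
library(isletmap)

res <- run_islet_pipeline(islet_pipeline_config(seed = 42),
                          outdir = "islet_run")
str(res$summary)
```

```
List of 5
 $ seed        : int 42
 $ response    :List of 3
  ..$ mean_amplitude       : num 0.449
  ..$ mean_pulse_duration_s: num 3.01
  ..$ percent_responsive   : num 100
 $ connectivity:List of 4
  ..$ percent_connected_pairs: num 14.4
  ..$ mean_significant_C     : num 0.628
  ..$ hub_fraction           : num 0.14
  ..$ n_hubs                 : int 7
 $ spectral    :List of 1
  ..$ median_dominant_period_s: num 5.25
 $ stain       :List of 2
  ..$ n_cells_segmented   : int 30
  ..$ low_fraction_percent: num 20
```

Reading the output: every cell responded to the glucose step
(`percent_responsive`), with a mean F/F_min rise of ≈ 0.45 over baseline
and ≈ 3 s Ca²⁺ pulses. About 14% of active-cell pairs were significantly
co-active, and 7 of 50 cells (14%) were classified as hubs — the simulator
planted 10%. The population's dominant oscillation period was ≈ 5 s, and
the stain stage segmented all 30 synthetic nuclei, 20% of which fell in
the PDX1^LOW (bottom three bins, 0–15 normalized units) range — exactly
the planted LOW fraction.

The run directory contains per-stage CSVs (traces, rasters, C and p
matrices, node/edge tables, wavelet power, cell tables, distributions),
PNG figures (raster plot, connectivity map, spectrum heat map), the
machine-readable `summary.json`, the resolved `config.json`, and a run
log. Individual stages are available as plain functions
(`generate_islet_traces()`, `normalize_traces()`, `detrend_denoise()`,
`binarize_activity()`, `coactivity_matrix()`,
`permutation_significance()`, `classify_hubs()`, `morlet_cwt()`,
`measure_cells()`, `intensity_distribution()`, `ctcf()`, …); see the
vignette in `vignettes/islet-functional-mapping.Rmd` for the methods and
the reasoning behind every default.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/islet-pipeline.R --seed 42 --outdir islet_run
```

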