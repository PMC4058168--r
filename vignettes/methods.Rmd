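---
title: "Methods: wall-motion mapping and spectral screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wall-motion mapping and spectral screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartwave)
```

This vignette documents the numerical methods behind each stage of the
`cartwave` pipeline, the units and defaults of every tunable parameter, and
the design decisions that are not obvious from the API reference. It is the
place to look when a number in the output needs to be traced back to a
formula.

## 1. The physical picture

A longitudinal B-mode scan of the common carotid shows the far wall as a
bright, roughly horizontal band. With each cardiac cycle the wall distends
radially, and the distension does not happen simultaneously along the
vessel: a wave of motion propagates longitudinally. In a healthy young
vessel the wall moves nearly as a unit — adjacent segments trace almost
identical waveforms, offset only by the propagation delay. With ageing and
disease the wall stiffens heterogeneously; different segments respond with
different amplitudes and local frequency content, so the motion decoheres
along the vessel.

`cartwave` quantifies that coherence. It extracts one radial-motion signal
per region of interest (ROI) along the wall, stacks them into a
spatiotemporal map (time × position), Fourier-transforms each ROI's signal
into a spatiospectral map (frequency × position), and reduces the map to
two scalar homogeneity features that support a threshold-based screening
call.

## 2. Synthetic phantom

Real annotated sequences are scarce, so the package ships a phantom
generator with exact ground truth (`phantom_config()`,
`generate_phantom()`). The phantom is first-class code: every quantitative
claim in the test suite is made against it.

### 2.1 Geometry and image formation

Frames are `height × width` gray-level matrices in `[0, 1]` (defaults
128 × 256, 120 frames at 30 fps, 3 cardiac cycles). Three horizontal
regions — lumen (intensity 0.1), wall band (0.9), outer tissue (0.5) —
are separated by the moving inner boundary `b(x, f)` (column `x`, frame
`f`) and the wall thickness (defaults: baseline boundary row 60, thickness
12 px, both scaled proportionally when `height` differs from 128).
Rows use a continuous convention: boundary value `v` is the interface
between pixel rows `v` and `v + 1`, and a pixel row straddled by the
boundary gets the area-weighted mixture of the two region intensities, so
the phantom is sub-pixel-exact by construction.

Two features make the images ultrasound-like rather than cartoon-like:

* **Scatterer-locked speckle.** A multiplicative log-normal speckle field
  (`speckle_scale`, default 0.05) is sampled once per sequence in a
  coordinate frame attached to the tissue and advected with the wall
  motion. Speckle that moved with the tissue is what makes texture-based
  tracking meaningful; regenerating noise per frame would instead simulate
  electronic noise and destroy the temporal-feature contrast the
  segmentation relies on.
* **Double-line wall echo.** The wall band is darkened by
  `0.45 · sin²(π · rel / 1)` of its depth fraction `rel`, reproducing the
  intima–media–adventitia double-line pattern: two bright edges around a
  darker media. This is why the segmentation needs an explicit band-filling
  step (§3.3) — a naive intensity threshold splits the wall in two.

### 2.2 Motion model

Each column's boundary is

```
b(x, f) = wall_row − amplitude · A(x) · [ sqrt(1 − ρ(x)²) · s(u) + ρ(x) · sin(2π q(x) u + ψ(x)) ]
```

evaluated at the delayed cycle phase `u` of `τ = f − x / wave_speed`
(`wave_speed` in px/frame, default 8; `Inf` gives exactly simultaneous
motion). `s(u)` is the category waveform: a damped sinusoid
`sin(2π k u) e^(−d u)` with `(k, d)` = (3, 1) for `young`, (2, 2.5) for
`elderly`, (2, 0.8) for `cad`, each normalized to unit peak. Cycle-to-cycle
irregularity adds per-cycle phase and gain jitter scaled by the
`irregularity` parameter.

Spatial heterogeneity enters twice, both scaled by `heterogeneity`:

* amplitude modulation `A(x) = 1 + het · 0.5 · sin(3π x)`;
* **energy mixing**: a fraction `ρ(x)² ` of each column's motion energy is
  diverted from the shared waveform into a column-local oscillation of
  local frequency `q(x)` and phase `ψ(x)`. The `sqrt(1 − ρ²)/ρ` split keeps
  the total signal energy approximately constant, so heterogeneity changes
  *where the spectrum lives along the wall* without changing how much
  motion there is — which is exactly the axis the spectral features are
  supposed to measure. `ρ` is capped at 0.95 so the shared waveform never
  vanishes entirely.

Category presets: `young` (heterogeneity 0, irregularity 0, amplitude
2 px), `elderly` (0.5, 0.1, 1.2 px — weaker as well as slower motion),
`cad` (1.0, 0.5, 2 px). All presets can be overridden per parameter.

The generator returns the exact boundary `truth$boundary` and the reference
wall mask `truth$wall_mask`, plus a synthetic ECG with R-peaks at cycle
starts.

## 3. Segmentation

### 3.1 Features

On the temporal-median reference frame, three spatial texture features are
computed per pixel over a 9 × 9 window with symmetric (reflected) border
padding (`compute_spatial_features()`): window mean, population standard
deviation, and Shannon entropy in bits over a fixed 16-bin intensity
histogram. A fourth feature, the per-pixel *temporal* population standard
deviation across all frames (`compute_temporal_std()`), is what singles out
the moving wall among equally bright static structures.

### 3.2 Clustering and dynamic-cluster selection

Each feature channel is z-scored and the pixels clustered with
`stats::kmeans` (k = 3, 10 restarts, fixed seed → deterministic). Among
clusters whose mean intensity exceeds the global median (a visibility
guard), `select_wall()` picks the one with the largest mean temporal
standard deviation — the most dynamic visible structure. A scene whose
winning cluster falls below `min_dynamism` (default 1e-3) raises a classed
`cartwave_no_wall` error rather than returning garbage. The mask is
morphologically closed and reduced to its largest 4-connected component.

### 3.3 Reference-frame refinement

The temporal features mark the whole region *swept* by the moving wall over
the sequence, which is systematically thicker than the wall band at any one
instant. `segment_wall()` therefore refines the cluster to the reference
frame: Otsu's threshold is computed on the reference intensities inside the
cluster, and each column is filled between its outermost bright rows. The
filling step bridges the darker media line of the double-line echo (§2.1);
without it the mask splits into two thin stripes. If thresholding retains
less than 25 % of the cluster the refinement is abandoned as not credible
and the unrefined mask is kept.

On default phantoms this yields Dice overlap 0.89–0.92 against the true
wall band across all three categories.

## 4. Boundary tracking and ROI signals

`boundary_track()` locates, per column and frame, the lumen-side
half-maximum crossing of the intensity profile, with linear interpolation
between samples — sub-pixel by construction, in the same continuous row
convention as the phantom. Columns where direct detection fails are
interpolated from neighbors; the *valid span* is the longest run of columns
with at least 90 % direct detections, and all downstream stages use only
that span. If no usable span exists, a `cartwave_no_boundary` error is
raised. On default phantoms the tracked boundary agrees with ground truth
to ~0.07 px RMSE.

`assign_rois()` tiles the valid span with midway-overlapping windows: width
`w` (even), stride `w/2`, giving `R = floor((L − w) / (w/2)) + 1` ROIs over
`L` columns. By default `w` is chosen to target ~16 ROIs.
`extract_radial_signals()` averages the boundary over each ROI per frame,
orients the sign so that outward distension is positive (the lumen is above
the far wall in the image), and removes each ROI's temporal mean.

## 5. Maps and spectral features

`build_spatiotemporal()` stacks the signals as a frames × ROIs matrix.
`build_spatiospectral()` removes each column's mean, applies `mvfft`, and
keeps one-sided magnitudes `|X_k| / n` for bins `1 … n/2` on the normalized
frequency axis `k / (n/2)` (1.0 = Nyquist). Parseval's identity for this
normalization is verified in the test suite to 1e-9.

From the spatiospectral map, `case_features()` derives:

* **Mean spectrum and its area** (`mean_spectrum()`): across-ROI average
  spectrum; its trapezoid-free plain average is reported as
  `mean_spectrum_area`.
* **FT2 area** (`ft2_feature()`): the mean spectrum, mean-removed, is
  Fourier-transformed a second time; `ft2_area` is `100 · (2/F) · Σ|FT2| / F`
  over the one-sided bins. A homogeneous wall gives a nearly periodic,
  peaky mean spectrum whose second transform concentrates energy — large
  area; heterogeneous motion smears it — small area.
* **Ramp feature** (`ramp_feature()` of `std_curve()` +
  `spectral_envelope()`): the across-ROI standard deviation per frequency
  bin, max-normalized, envelope-interpolated across its strict local maxima
  (with an endpoint-chord dominance correction), then averaged under a
  frequency ramp: `log(mean(f · env(f)) + 1e-6)`. The ramp weights
  high-frequency spread; the log compresses the dynamic range; the 1e-6
  floor makes the all-zero case (perfectly coherent motion) well-defined at
  `log(1e-6) ≈ −13.8`.
* **Legacy band areas** (`legacy_spectral_areas()`): plain spectral areas
  over the full band and below 0.15 normalized frequency, kept for
  comparability with older single-signal analyses.

### A documented limitation

Because the standard-deviation curve is max-normalized before the envelope,
the ramp feature measures the *shape* of the across-ROI spread, not its
magnitude. On tracked (rather than ground-truth) boundaries at zero
heterogeneity, the spread is dominated by flat tracking noise, which scores
*high* under the ramp — the opposite ordering to the noiseless theory. The
monotonicity of the ramp feature in heterogeneity is therefore guaranteed
(and tested) along the ground-truth route with simultaneous motion, while
full-pipeline classification leans on the FT2 area, which orders the
categories correctly under realistic noise. `calibrate_thresholds()` fits
each per-feature vote under the classifier's fixed polarity and neutralizes
a feature that does not order the calibration cohort in that direction,
rather than silently inverting the decision.

## 6. Classification

`classifier_config()` holds three thresholds: pathological votes fire when
`ft2_area` falls below `ft2_threshold` or `ramp_feature` rises above
`ramp_threshold` (ties resolve to healthy); non-pathological cases are
healthy-young-like iff `ft2_area` reaches `young_ft2_floor` with a negative
ramp vote. The default numbers (27.3, −0.1, 33.8) are the published
clinical separation lines; they are calibrated to that study's feature
scaling and are **not** transferable across normalizations — recalibrate
with `calibrate_thresholds()` for any new pipeline, as the worked example
in the README does for phantoms. Vote combination rules
(`either_positive` default, `either_agrees`, single-feature) and an
optional `suspected` margin are configurable. `cohort_metrics()` reports
the confusion table with pathological as the positive class;
`best_threshold_accuracy()` scans midpoints of sorted unique values plus
both extremes (the extremes cover the degenerate all-negative split) under
both polarities.

## 7. Problem sizes and budgets

The defaults — 128 × 256 px, 120 frames, 3 cycles, ~16 ROIs — were chosen
as the smallest sizes at which every stage operates in its intended regime:
enough frames for 40-sample cycles and stable spectra, enough columns for
16 non-degenerate ROIs, enough rows for the texture window not to dominate
the wall band. A full pipeline run takes a few seconds; the complete test
suite runs in ~5 minutes and the acceptance script in ~2.

## 8. Numerical conventions

* All indices are 1-based; frame `f`, column `x`, ROI `r`.
* Population (n-denominator) standard deviations throughout.
* Entropy in bits (`log2`).
* One-sided DFT magnitudes `|X_k|/n`, bins `1 … n/2`, normalized frequency
  `k/(n/2)`.
* Errors carry classes (`cartwave_no_wall`, `cartwave_no_boundary`,
  `cartwave_format_error`, `cartwave_file_error`) so callers can branch on
  failure mode.
* Every stochastic step takes an explicit seed; identical inputs and seeds
  give bit-identical outputs.
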