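---
title: "Shape-based discrimination and motility analysis of lung immune cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-based discrimination and motility analysis of lung immune cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roundtrack)
```

## Overview

`roundtrack` analyses two-channel time-lapse two-photon movies of lung
tissue in five stages: drift correction, segmentation with roundness scoring,
track linking, per-track motility metrics, and shape-based classification,
followed by nonparametric group comparisons. This vignette documents the
model behind each stage, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## Drift correction

Lung explants drift during imaging by roughly as much as the cells move, so
registration precedes everything else. The second-harmonic (SHG) collagen
channel is structurally static and serves as the spatial reference; the cell
channel never enters the shift estimation, it only receives the recovered
transform.

`estimate_shift()` searches all integer translations within
`max_shift_px` (default 50 px, about 27 µm at the default calibration of
280 µm / 512 px) for the one maximizing the normalized cross-correlation
between the two images, computed over the actual overlap window with
zero-mean, unit-variance normalization. The correlation surface is evaluated
with the FFT decomposition of windowed sums, so the search is exhaustive
without being quadratic in image size. Normalized rather than raw correlation
is used because it is insensitive to slow intensity changes (laser power,
photobleaching of background autofluorescence).

`correct_drift()` registers each frame against the **previous aligned frame**
(sequential pairwise) by default: a residual step is estimated after
pre-aligning with the previous cumulative shift, which keeps each search small
and tolerates slow morphological change in the tissue. Registration against
frame 0 is available via `reference = "first"` for scenes where error
accumulation is a concern. Shifts are integer pixels; an optional parabolic
subpixel refinement (`subpixel = TRUE`, default off) interpolates the
correlation peak. Only rigid translation in the projection plane is modelled:
rotation, scaling and axial (z) drift are out of scope, matching an analysis
that operates on maximum-intensity projections (`max_project()`).

Degenerate inputs: a constant (zero-variance) image makes correlation
undefined and raises an error rather than returning an arbitrary shift; a
registration failure is reported with the frame index. A configurable
`min_correlation` warns when the peak correlation is suspiciously low (e.g.
the tissue moved out of the field).

## Segmentation and the roundness coefficient

Cells are segmented per frame (`segment_cells()`): Gaussian smoothing
(`smoothing_sigma_px`, default 1 px), binarization (Otsu's threshold by
default; a fixed threshold is available for images with calibrated
intensities), optional hole filling, 8-connected component labelling, then
filtering by area (defaults 10–1500 µm², bracketing single myeloid cells) and
removal of border-touching components, whose truncated outlines would corrupt
the shape measurement.

Each surviving component is scored with the Instantaneous Roundness
Coefficient,

$$\mathrm{IRC} = \frac{4\pi A}{P^2},$$

the classical isoperimetric circularity: exactly 1 for a circle, $\pi/4
\approx 0.785$ for a square, and tending to 0 for line-like shapes. This is
the unique classical index with that range and those endpoint shapes.

The perimeter estimator matters more than it looks: counting boundary pixels
overestimates $P$ for diagonal boundaries erratically and can push the index
far from 1 even for perfect disks. `crofton_perimeter()` therefore uses a
four-direction Cauchy–Crofton intercept count — boundary crossings along
rows, columns and both diagonals, weighted by line spacing — which keeps
rasterized disks of radius ≥ 15 px within 0.05 of 1. Residual digitization
overshoot is clamped so the IRC always lies in [0, 1]. Centroids are
unweighted binary-mask centroids (an intensity-weighted option exists);
coordinates are 0-based pixel centres, x = column, y = row, converted to µm
with `pixel_size_um` (default 280/512).

## Track linking

`link_detections()` implements frame-to-frame assignment in the tradition of
the classical multiple-particle tracking codes: among all one-to-one pairings
between open track ends and current-frame detections within
`max_displacement_um × gap`, it selects the pairing that links the most cells
and, among those, minimizes the total squared displacement. The candidate
graph is decomposed into connected components and each component is solved
exactly by branch-and-bound, so the result equals exhaustive enumeration (the
test suite verifies this on randomized instances). Defaults:
`max_displacement_um = 20` (10 µm/min at 2-min sampling, above lung immune
cell speeds), `memory_frames = 1` (a single missed detection may be bridged),
`min_track_length = 3`. Shape plays no role in the linking cost — roundness
is an output of tracking, not an input, which keeps classification
independent of tracking.

Bridged gaps contribute no IRC samples and one straight-line segment to the
path length: unobserved positions must not fabricate roundness data.
`track_summary()` reports both `duration_min = (n−1)·Δt` (elapsed time
between first and last observation) and `observation_time_min = n·Δt` (the
per-frame convention under which a cell observed on 16 two-minute frames is
said to be followed for 32 minutes); both conventions circulate in the
motility literature and making each explicit avoids off-by-one confusion.

## Per-track metrics

For a track observed at positions $p_1,\dots,p_n$:

- **MRC** $= \frac{1}{n}\sum_t \mathrm{IRC}_t$;
- **MD** $= \max_t \lVert p_t - p_1 \rVert$;
- **MI** $= \lVert p_n - p_1\rVert \big/ \sum_t \lVert p_{t+1}-p_t \rVert$,
  in [0, 1] by the triangle inequality;
- **velocity** $=$ path length / elapsed time (µm/min) — the mean
  instantaneous speed. The alternative definition, net displacement over
  time, equals MI × velocity and is derivable from the output, so only one is
  stored.

A stationary track has zero path length and MI is defined as 0 (with a
`stationary` flag) rather than dropping the cell. All distances are 2D
projected distances in µm after drift correction.

## Classification

The MRC distribution of a mixed population is bimodal: dendritic-shaped cells
concentrate at low roundness, round cells at high roundness.
`build_mrc_histogram()` bins MRC values over [0, 1] (default bin width 0.05;
bins are right-closed, so an interior edge value falls in the lower bin) and
`fit_double_gaussian()` fits

$$a_1 e^{-(x-\mu_1)^2/2\sigma_1^2} + a_2 e^{-(x-\mu_2)^2/2\sigma_2^2}$$

to the bin-centre counts by Levenberg–Marquardt least squares. Initialization
is deterministic — means at the two most separated substantial histogram
peaks (≥ 10% of the tallest, which ignores stray single-count bins), sigmas
at a quarter of the peak separation, amplitudes at the peak heights — so
repeated runs give identical fits with no random restarts. $R^2 = 1 -
SS_{res}/SS_{tot}$ is reported against the counts, the natural goodness
measure for a histogram-curve fit. The fit refuses unimodal or sparse
histograms (< 8 nonzero bins, or < 2 smoothed modes) with an informative
error instead of producing a silent threshold.

`find_threshold()` locates the local minimum of the fitted curve strictly
between the means (fine grid, then golden-section refinement); overlapping
components with no interior valley are an error. The empirical between-peak
dip is reported alongside as a diagnostic. `classify_tracks()` labels tracks
below the threshold DSC and at or above it RSC — the tie at exactly the
threshold goes to RSC, a documented convention since strict inequalities on
both sides would leave equality unassigned.

For routine analysis a **fixed threshold of 0.35** is the default operating
mode (`run_pipeline(mrc_threshold = 0.35)`): a single short movie yields a
few dozen MRC values, too few for a stable mixture fit, whereas 0.35 is the
established operating point for this cell system. Fitting is recommended when
several hundred tracks are pooled; `run_pipeline(mrc_threshold = NULL)`
switches to the fitted threshold.

## Group statistics

`mann_whitney()` wraps the two-sided Mann–Whitney U test: exact enumeration
when the smaller sample has ≤ 8 values and no ties, tie-corrected normal
approximation with continuity correction otherwise. Sidedness is two-sided
throughout — no direction of effect is assumed. `significance_stars()` maps p
to `*` < 0.05, `**` < 0.01, `***` < 0.0001 (note the three-star cut at
10⁻⁴, not the more common 10⁻³ — implemented as printed in the original
figure convention). `compare_groups()` runs every metric × contrast, treating
each track as one statistical unit (one symbol per cell; no animal-level
nesting, matching the pooling convention of the source experiments). No
multiple-testing correction is applied to the starred p-values; a
Holm-adjusted column is emitted alongside for transparency.

## The synthetic-data generator

No public two-channel lung movie with ground truth exists, so validation
rests on simulation (`simulate_movie()`, `simulate_track_table()`). The
generator emulates the acquisition regime: 512 × 512 px covering
280 × 280 µm, one projected frame every 2 minutes for an hour (31 frames).
Defaults, chosen once as a realistic operating point:

| parameter | default | rationale |
|---|---|---|
| round cell radius | 5 µm | monocyte-scale body |
| round cell speed | 4 µm/min | fast patrolling monocyte-like movers |
| dendritic body / arms | 3 µm + 5 arms × 12 µm | dendritiform outline with reliably low IRC |
| dendritic speed | 1.5 µm/min | slower resident-cell movement |
| drift | integer random walk, sd 2 px/frame | slow tissue drift of the same order as cell motion |
| noise | Gaussian, sd 0.02 of unit intensity | mild detector noise |

Cells perform isotropic random walks (fixed step `speed × Δt`, uniform
heading — the simplest motion model with controllable speed and MI < 1) and
reflect at the field margins so no track is censored in short test movies.
Dendritic cells are star polygons with fixed per-cell orientation; their IRC
(~0.1–0.2) and that of disks (~0.95–1) bracket the 0.35 threshold widely. The
structural channel renders random smoothed line segments — a texture with
nonzero autocorrelation, which is the property registration needs — on a
canvas larger than the field, then cuts each frame at the drifted offset, so
a noiseless movie is an exact integer translation of a static scene and drift
recovery can be tested for exactness. Drift is generated from the
configuration seed, so the structural channel, the cell channel and the
exported ground truth always share the same trace. Ground-truth positions are
recorded before drift, in µm.

The generator deliberately does **not** emulate: optics (no PSF, the cells
are binary masks before noise), photobleaching, cell–cell contact and
overlap, shape change over time beyond rasterization jitter, out-of-focus
loss, or 3D motion. Passing tests therefore demonstrate the correctness of
the algorithms under controlled conditions — exact drift recovery, perfect
linking, near-perfect classification — not performance on real tissue, where
segmentation quality is the binding constraint.

## Problem sizes used in the shipped tests

The test suite and the acceptance script run reduced scenes chosen as the
smallest sizes that exercise every code path: 128–320 px fields, 6–12 frames,
4–16 cells per movie, 3–10 simulation seeds per property, 10,000-sample MRC
histograms for mixture recovery, and 200 null replicates for the type-I-error
check. The defaults of `simulation_config()` remain the full-scale regime.

## Known limitations

- Rigid integer translation only; rotation or elastic tissue deformation will
  degrade registration.
- Touching cells merge into one component (no watershed splitting); the area
  ceiling discards most such fusions instead of mislabelling them.
- The velocity definition (path/duration) is one of two conventions in use;
  absolute velocities are only comparable across studies using the same one.
- The double-Gaussian fit needs several hundred pooled MRC values; per-movie
  fitting of small fields is intentionally refused.
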