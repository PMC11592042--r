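---
title: "Methods: pipeline model, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pipeline model, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorstack)
```

This vignette documents the scientific model behind `fluorstack`, the
parameters that matter, the design decisions taken where the design was
genuinely open, and what the synthetic validation does and does not
establish about real data.

## The analysis model

The package treats a recording as a `T`-frame stack of 8-bit images with a
frame rate `f` (Hz), mapping frame `k` to time `t = (k − 1)/f`, so frame 1
is `t = 0`. All intensity arithmetic is carried out in floating point and
quantized exactly once per operator (round half up, clip to `[0, 255]`),
so chained operators never accumulate mid-operator rounding bias.
Non-8-bit input is rescaled by a single *global* min–max over the whole
stack rather than per frame; a per-frame rescale would silently destroy
the relative intensity changes over time that the entire downstream
analysis measures.

**Segmentation happens once, on a reference image.** The default
reference is the maximum-intensity projection (per-pixel max over time),
which guarantees that a cell fluorescing only late in the recording is
still present in the image being segmented; the first frame is available
as an alternative for recordings where baseline fluorescence already
outlines all cells. The classical backend is: Gaussian smooth
(`smooth_sigma`, default 2 px) → global Otsu threshold → 4-connected
components → drop components outside `[min_area, max_area]` (default
`[10, Inf)` px) → relabel contiguously in raster order of each
component's first pixel. It is fully deterministic, which is what makes
byte-identical reruns and hash-based regression tests possible. Its
assumption — ROIs brighter than background, separable by one global
threshold — matches the fluorescence-soma setting; its known limitation
is that touching cells are not split (no shape prior). The `stardist`
backend slot keeps the interface open for a star-convex CNN segmenter,
which handles touching cells, at the cost of a model download; it is not
available in this installation and requesting it raises an instructive
error rather than silently degrading.

**Traces.** For label `l` with pixel set `P_l`, the trace is the
unweighted mean intensity over `P_l` per frame, taken from the
background-corrected stack when a background rectangle was supplied (the
background scalar is the mean of the rectangle in frame 1 — the
subtraction must not itself vary over time, or it would distort trace
kinetics; a per-frame variant exists as an explicit option). The
background-corrected stack is deliberately *not* used for segmentation:
correction can clip dim rims and change component shapes.

**Bright-pixel area.** With area threshold `θ` (default 0.3) and
`M_l = max` intensity of label `l` over the *whole stack*, the bright
area at frame `t` counts pixels above `θ·M_l`. Using a stack-wide rather
than per-frame maximum is essential: a per-frame maximum would normalize
away exactly the area changes (swelling, shrinking, spatial spread) the
quantity exists to measure.

**ΔF/F and kinetics.** Each trace is smoothed by a centered moving
average (odd `window`, truncated and renormalized at the ends; window 1 =
identity), normalized as `y = (F − F₀)/F₀` with `F₀` a single frame or
the mean of a baseline window, and summarized by six parameters measured
on the smoothed, normalized trace: rise time `t(peak) − t(base)`, decay
time `t(recovery) − t(peak)`, duration (their sum — an exact identity,
enforced by construction), amplitude `y[peak] − y[base]`, and rise/decay
rates. The default rate definition is the reciprocal of the corresponding
time; an amplitude-per-time ("slope") definition is available via
`rate_mode`. Reciprocal rates were chosen as the default because cohort
statistics of rise/decay times and rates reported for this class of
experiment are mutually consistent under the reciprocal reading (mean
rates exceed the reciprocal of mean times, as Jensen's inequality
requires) and inconsistent with the slope reading by an order of
magnitude. The `base` frame used for the amplitude is the last baseline
frame.

**Automatic peak/recovery.** In dynamic mode the peak is the argmax after
the baseline window (earliest frame on ties) and the recovery point is
the first frame after the peak at which the trace has returned to within
`recovery_fraction` (default 0.1) of the amplitude above the baseline
mean. A trace that never recovers is flagged (`recovery = T`,
`did_not_recover`) rather than silently truncated; a trace whose
post-baseline maximum does not exceed the baseline mean raises a
"no transient" condition, which the pipeline records as a flagged `NA`
row. The 10%-return criterion is this package's own definition of
"recovery point" — any threshold rule fires strictly before a linear
decay actually reaches baseline, so validation compares the detector
against the same rule applied to the noise-free truth trace (see below).

**Photobleaching correction.** Bleaching is modeled as a mono-exponential
`y(t) = a·e^{−bt} + c` with `b ≥ 0`, fitted by least squares to the
normalized trace at the union of the baseline and recovery windows only
(typically the first and last 10 frames) — the frames where no evoked
signal is present — then subtracted point by point over all frames. The
fit is computed by profiling `b`: for each candidate `b` the linear pair
`(a, c)` has a closed-form least-squares solution, and the 1-D profile is
minimized by golden-section search on `[0, 100/span]` with tolerance
1e−13. This is deterministic, honors the `b ≥ 0` bound exactly, and
cannot fail to converge; ties against `b = 0` are broken toward `b = 0`
(no bleaching), where the model degenerates to a constant and the
solution `a = 0, c = mean` is used directly. An independent
Levenberg–Marquardt fit (`minpack.lm`) is used in the test suite as a
cross-check oracle, never as the implementation. An optional
`shift_nonnegative` step subtracts the absolute minimum of the corrected
trace, preserving all pairwise differences while removing negative
values.

**Correlation.** The cell–cell matrix is the Pearson correlation of the
raw mean-intensity traces (smoothing is available upstream but is not
applied implicitly). Constant traces have mathematically undefined
correlation; those entries are reported as `NA`, never as 0 — reporting 0
would fabricate evidence of independence.

## The synthetic generator

Stacks are generated as `F = B + O + N`: a flat background `B`, objects
`O` as cosine-tapered disks (star-convex, resembling fluorophore-loaded
somata), and i.i.d. Gaussian noise `N`, summed in floating point, clipped
to `[0, 255]` and quantized. The rim taper floors at 0.5 of the peak so
that, at zero noise, every pixel inside the programmed disk exceeds the
0.3 area threshold while background pixels never do — making the
rasterized disk area the exact ground truth for the bright-pixel count.
SNR is defined as `sqrt(var(F)/var(N) − 1)`; because signal and noise are
independent, the noise σ achieving a target SNR is obtained in closed
form from the noise-free stack's variance, and fixtures are parameterized
so that clipping stays below ~0.1% of voxels (measured ≈ 2×10⁻⁵ for the
multi-object fixture), keeping the variance identity — and hence the
calibration — valid.

Fixture geometry is a package constant, chosen once: the multi-object
benchmark is 256×256×150 with background 60 and seven radius-6 disks of
peak 120 (five present in frames 1–148, two only in frames 149–150, all
footprints disjoint); single-object and swelling fixtures are 96×96×150
with background 50 and a radius-8 disk (baseline center intensity 100,
transient amplitude 50) or a constant-150 disk whose radius ramps
6 → 12 → 6. The default multi-object SNR is 0.5, the documented floor at
which exact 7-object counting holds across seeds. An optional
multiplicative `e^{−t/τ}` envelope emulates photobleaching for
bleach-correction validation; the τ used in tests (3000 s for a 150 s
recording, ≈5% total loss) represents mild bleaching — under a
*multiplicative* envelope the additive correction leaves a residual
amplitude bias of factor `e^{−(t_peak−t_base)/τ}`, so strong bleaching is
intentionally out of the validated regime.

What the generator does *not* emulate: optics (no PSF), motion, uneven
illumination, photon (Poisson) statistics, overlapping or moving cells,
and indicator nonlinearity. Passing the synthetic suite therefore
demonstrates correctness of the *computations* under the stated model —
not segmentation robustness on arbitrary real tissue, where the
pre-processing options and, for touching cells, a shape-prior backend
carry the burden.

## Validation design and problem sizes

The test suite validates each stage against independent oracles:
brute-force loop implementations (median filter, background subtraction,
moving average, disk-minimum filter, Pearson formula) on small frames;
closed-form identities (SNR estimator vs direct variance ratio,
duration = rise + decay); and ground-truth recovery on generated stacks —
7/7 object counts at SNR 0.5 across five seeds on the 256×256×150
benchmark, trace correlation > 0.95 against truth at SNR ≥ 1, exact
bright-area and landmark recovery at zero noise, amplitude within 5% and
landmarks within ±2 frames at SNR 1, and bleach-fit recovery of `1/τ`
within 5% with amplitude restored within 2%. Determinism is checked by
hash-comparing complete CSV/TIFF output bundles across reruns. Kinetic
recovery is measured on the smoothed trace (window 5), mirroring the
pipeline's own procedure, with the truth reference computed by applying
the identical analysis to the noise-free trace. These sizes keep the
whole suite under a few minutes on one CPU while leaving every claim
at the stack dimensions the generator documents (150 frames).

## Known limitations

- One transient per trace: no multi-peak/event detection or deconvolution.
- The classical backend does not split touching cells and re-segments
  nothing over time (one reference image per run; no tracking).
- Bright-area swelling readout is indirect and assumes a morphology-inert
  dye; for dyes that brighten as signal spreads it conflates area with
  intensity, and it is only validated here under the synthetic model.
- Bleach correction assumes signal-free baseline and recovery windows and
  mild mono-exponential bleaching; multiplicative bleach leaves the small
  amplitude bias quantified above.
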