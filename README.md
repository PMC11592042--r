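# fluorstack

Headless segmentation and kinetic analysis of time-lapse fluorescence
microscopy image stacks.

Ion-imaging experiments (e.g. Na⁺ or Ca²⁺ indicators in brain-slice
neurons and astrocytes) produce multi-frame TIFF stacks in which
fluorophore-loaded cell bodies must be found, their fluorescence followed
over time, and the evoked transients summarized. Doing this by hand —
drawing ROIs, picking baseline/peak/recovery frames per cell — is slow and
user-dependent. `fluorstack` is a scriptable engine for that workflow:
every choice lives in a declarative configuration, so a run is exactly
reproducible, and a synthetic-stack generator with known ground truth lets
each stage be validated quantitatively.

## What it computes

Given a `T`-frame 8-bit stack, the pipeline:

1. **Pre-processes** frames (background subtraction from a user rectangle,
   Gaussian/median blur, brightness–contrast, CLAHE, rolling-ball
   background correction), in a declared order.
2. **Segments** once on a reference image — the maximum-intensity
   projection `MIP(r,c) = max_t F(t,r,c)` (so cells appearing late are
   still caught) or the first frame — into a labeled ROI map
   (deterministic classical backend: Gaussian smooth → Otsu threshold →
   4-connected components → area filter).
3. **Extracts per-ROI traces**: mean intensity per frame, plus the
   *bright-pixel area* `#{p : F(t,p) > θ·M_l}` with `θ = 0.3` of the ROI's
   stack-wide maximum `M_l` — an indirect readout of cell swelling /
   shrinking over time.
4. **Post-processes each trace**: moving-average smoothing, ΔF/F
   normalization `y = (F − F₀)/F₀` against a baseline window, optional
   photobleaching correction by subtracting a mono-exponential
   `a·e^(−bt) + c` fitted only on the baseline and recovery windows, and
   automatic peak/recovery detection.
5. **Summarizes kinetics** per ROI with six parameters: rise time, decay
   time, duration (= rise + decay, always), rise rate, decay rate
   (reciprocal times by default) and ΔF/F amplitude; plus per-cell
   centroids and the cell–cell Pearson correlation matrix of the traces.

The synthetic module generates stacks from `F = B + O + N` (flat
background, tapered disks, Gaussian noise) with the noise σ calibrated to
a target `SNR = sqrt(var(F)/var(N) − 1)`, and returns the exact ground
truth (label map, noise-free traces, per-frame disk areas) against which
the whole pipeline is tested.

## Worked example

Analyze a synthetic single-cell transient (baseline frames 1–9, linear
rise to frame 60, recovery by frame 110, at SNR 2):

```r
library(fluorstack)

g   <- generate_stack(single_object_fixture(seed = 1, snr = 2))
estimate_snr(g$stack, g$truth$noise_stack)   # 2.0003

cfg <- run_config(frame_rate_hz = 1,
                  segmentation = segment_params(smooth_sigma = 1, min_area = 20),
                  baseline = baseline_spec("dynamic", 1:9),
                  smoothing_window = 5)
res <- run_pipeline(cfg, stack = g$stack)
summary(res)
#> Pipeline result: ok
#>   labels: 1, frames: 150, frame rate: 1 Hz
#>   kinetic parameters:
#>  label rise_time_s decay_time_s duration_s amplitude flag
#>      1          51           46         97 0.2775253
```

One cell is found; its detected peak frame is 60 (the programmed value)
and the automatic recovery point lands at frame 106, where the smoothed
ΔF/F has returned to within 10% of the amplitude above baseline — hence
rise 51 s from the end of the baseline window, decay 46 s, duration 97 s,
rates 0.0196 s⁻¹ and 0.0217 s⁻¹, and a ΔF/F amplitude of 0.28 (the
footprint-mean of the programmed 50% center rise). `export_csv(res, dir)`
writes `traces.csv`, `normalized.csv`, `params.csv`, `centroids.csv`,
`correlation.csv` and a checksummed manifest; with `cfg$outdir` set the
pipeline writes them (plus the 16-bit label TIFF) itself.

A thin CLI wraps the same functions:

```sh
exec/fluorstack synth --fixture multi --seed 1 --out demo
exec/fluorstack segment --input demo/stack.tif --rate 1 --out demo_seg
```

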