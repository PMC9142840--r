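---
title: "Quantifying multimodal nonlinear optical images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multimodal nonlinear optical images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nloiquant)
library(dplyr)
```

Label-free multiphoton imaging of fresh tissue combines four contrasts in
one pass: two- and three-photon excited autofluorescence (2PF, 3PF),
dominated in tissue by FAD and NAD(P)H respectively, and second- and
third-harmonic generation (SHG, THG), which highlight collagen fibers and
optical interfaces such as cell membranes and lipid droplets. This
vignette explains the three quantitative methods the package implements
on top of such data — Fourier-domain fiber orientation analysis, optical
redox ratio profiling, and longitudinal trajectory analysis — along with
the synthetic scene generator used to validate them, the parameters that
matter, and the numerical choices behind the implementation.

## Fiber orientation from the SHG power spectrum

Collagen organization differs between tumor, margin, and fibrotic tissue:
co-aligned bundles versus dense random networks. Rather than tracing
individual fibers morphologically (iterative, and sensitive to signal
strength), `angular_spectrum()` works in the frequency domain. The SHG
raster is mean-subtracted, windowed (Hann by default), and 2-D Fourier
transformed; the power spectrum is then integrated over rotating angular
wedges. A fiber at angle $\theta$ in image space concentrates its
spectral power along $\theta + 90^\circ$, so the implementation applies
that rotation internally and always reports *fiber* angles — omitting
this step is the classic mistake in Fourier-transform SHG analysis, and
it silently shifts every result by 90°.

The wedge energies, normalized to sum to one, form an angular
distribution $E(\theta_k)$ on $[0^\circ, 180^\circ)$ (fiber angles are
undirected). Two summary statistics follow:

- the **dominant angle**, $\arg\max_k E(\theta_k)$ (ties broken toward
  the smaller angle), and
- the **alignment ratio** $\mathrm{AR} = \max_k E(\theta_k) \,/\,
  \operatorname{mean}_k E(\theta_k)$, which is 1 for a perfectly flat
  distribution and equals the number of wedges for a one-hot
  distribution.

Because the one-hot bound depends on the binning, AR values are only
comparable between analyses run at the same angular step; the package
default is 1° (180 wedges). All filter parameters are exposed in
`angular_filter_params()`, none being canonical:

| parameter | default | rationale |
|---|---|---|
| `angle_step_deg` | 1° | resolves narrow orientation peaks; 180 wedges |
| `wedge_half_width_deg` | step/2 | abutting wedges, total energy preserved |
| radial band | 1/(20 µm) – Nyquist | passes fibers ~1–10 µm wide, blocks slow shading |
| `dc_block_radius_px` | 3 | removes residual DC leakage after mean subtraction |
| `window` | Hann | suppresses edge-discontinuity streaks in the spectrum |

Wedge membership is hard (binary), which keeps an independent brute-force
check exact: looping over every FFT bin and binning its power by
`atan2` angle reproduces the wedge energies to floating-point precision.
Non-square images are center-cropped to square before the FFT so
frequency sampling is isotropic. A constant raster has no in-band energy
and is rejected rather than returning an arbitrary flat distribution.
Normalization makes the distribution invariant to multiplying the image
by any positive constant, so results do not depend on detector gain.

```{r fibers}
scene <- generate_fiber_image(
  fiber_scene(image_size_px = 192, pixel_size_um = 0.7, n_fibers = 40,
              orientation = orientation_fixed(30), fiber_length_um = 50,
              seed = 7))
analyze_fibers(scene$shg, pixel_size_um = 0.7)
```

## Optical redox ratio profiling

The optical redox ratio is defined pixel-wise as

$$\mathrm{ORR} = \frac{\mathrm{2PF}}{\mathrm{2PF} + \mathrm{3PF}}
\;\approx\; \frac{\mathrm{FAD}}{\mathrm{FAD} + \mathrm{NAD(P)H}},$$

so lower values indicate a relatively more reduced, glycolytic state.
`orr_map()` computes the ratio wherever `2PF + 3PF` exceeds a validity
threshold (default 0, i.e. any fluorescence at all). The threshold exists
because a constant detector offset pushes background pixels toward
ORR = 0.5; on offset-corrected data the default is appropriate, and the
parameter is surfaced rather than hidden.

Distributions of pixel values are summarized by
`summarize_distribution()`: mean, median, SD, and the 25th/75th
percentiles with IQR = p75 − p25. All percentiles use the
linear-interpolation convention (R type 7), applied consistently here and
in the contrast-adjustment display transform. Masked analyses use
`segmentation_mask()` objects: one label raster applied identically to
every channel, so per-region statistics across channels always refer to
the same pixels. Both whole-frame and per-label pooling are first-class,
since practice mixes frame-level and segmented reporting.

Group differences are assessed with the tie-corrected Kruskal–Wallis
test (`compare_groups()`), with "not significant" defined as p > 0.05.
For three or more groups, all pairwise tests are reported both raw and
Holm-adjusted: pairwise p-values are often quoted without a stated
multiplicity correction, so the output carries both and flags them.

## Segmentation boundary

Instance segmentation of cells in real tissue is delegated to external
tools (typically a learned flow-based segmenter); the package ingests
their label masks via `load_mask()`, canonicalizing labels to a
contiguous `1..n` and splitting binary masks into 4-connected components.
4-connectivity avoids bridging adjacent cells through diagonal pixel
contacts. For synthetic fixtures and quick looks, `segment_blobs()`
provides a deterministic classical pipeline: Gaussian smoothing with
FWHM of a quarter of the expected cell diameter, Otsu threshold,
4-connected components, a 25%-of-expected-area size floor, and a
distance-transform watershed to split touching cells. One policy is worth
noting: a blob segmenter presumes blobs are a bright minority, so if the
Otsu threshold leaves most of the image "foreground" (featureless noise,
smooth gradients) the segmenter returns an empty mask rather than
inventing regions.

## Longitudinal trajectories

Fresh biopsy tissue degrades over roughly an hour of imaging, which shows
up as channel-specific intensity decay, a slow lateral drift of the field
of view, and a drifting redox ratio. `analyze_series()` bundles:

- **percent intensity change** per channel,
  $100 (\bar I_t - \bar I_0)/\bar I_0$, over whole-frame means (all
  pixels, mirroring frame-average reporting; masked variants available);
- **ORR trajectories** (whole-frame valid pixels and/or per-frame masks)
  with rank-based comparisons between selected timepoints — by default
  the first, middle, and last frame;
- **drift estimation** by phase correlation on a structural channel
  (default SHG, which decays least; the implementation falls back to the
  first non-constant channel). The normalized cross-power spectrum peak
  is refined to sub-pixel precision with a three-point parabolic fit,
  and the result is reported in micrometres as the vector mapping
  reference coordinates onto moving coordinates.

No drift correction is applied before computing trajectories — the
drifting field of view is analyzed as-is, matching how such series are
typically reported. Note that masks must be produced per frame when the
scene drifts appreciably: a static mask quickly stops overlapping the
cells it was drawn on.

## The synthetic scene generator

No deposited image data accompany the methods this package implements,
so validation rests on synthetic scenes whose ground truth is exact by
construction. The generator's defaults encode the study conditions the
methods target:

- **Fiber scenes** (`fiber_scene()`): anti-aliased straight capsules with
  angles drawn from a fixed value, a von Mises distribution on the axial
  circle (sampled by the Best–Fisher rejection method on doubled
  angles), or uniformly. Overlaps add, which is a deliberate
  simplification: SHG is coherent, but additive rendering suffices for
  testing orientation recovery.
- **Cell scenes** (`cell_scene()`): non-overlapping disks (rejection
  placement, 10⁴ attempts per cell) of radius 5 µm — a typical
  hepatocyte scale — whose interior pixels carry
  `2PF = ORR·B`, `3PF = (1−ORR)·B` so the pixel-wise ratio equals the
  requested per-cell ORR exactly; THG appears only on membranes and on
  lipid-droplet rings, droplet interiors are 3PF-bright, SHG is left to
  compose separately from fiber scenes.
- **Noise** (`noise_model()`): Poisson photon counting at `photon_scale`
  expected photons per unit intensity, plus Gaussian read noise and a
  constant offset, clipped at zero. The default scale of 40 photons is
  the experimentally motivated floor for reliable redox-ratio work.
- **Time series** (`decay_model()`, `simulate_time_series()`): each
  channel's intensity decays linearly in time to its configured total
  fraction — the simplest curve consistent with endpoint percentages;
  the default fractions 25/60/30/65% for 2PF/3PF/SHG/THG over 62 min
  are the degradation levels the analysis is designed to resolve. Drift
  accumulates linearly to `drift_um_total` (default study condition:
  15 µm across the series) and is applied by bilinear interpolation
  with periodic boundaries, emulating statistically stationary tissue
  entering the field of view as other tissue leaves — which also keeps
  the expected frame means exactly equal to the decay-scaled base
  means. An optional drug-response term multiplies 3PF by a
  piecewise-linear factor rising to `1 + amplitude` at `rise_end_min`
  (default 30 min, matching the reported transient NAD(P)H rise after
  an apoptosis inducer) and returning to 1 at the series end. The
  amplitude has no reported value and is deliberately a free parameter
  (default 0.8, large enough that the net 3PF trajectory is visibly
  unimodal against the decay).

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: optical point-spread blurring and
coherent SHG phase effects, axial defocus during degradation, spectral
cross-talk from other fluorophores (elastin, lipids, vitamin A),
non-circular and overlapping cells, and fiber curvature. The generator
validates the *estimators*, not the biology.

```{r series}
sc <- generate_cell_scene(cell_scene(image_size_px = 120, n_cells = 3,
                                     orr_targets = c(0.72, 0.86, 0.94),
                                     total_pf_brightness = 1, seed = 3))
series <- simulate_time_series(
  sc$frame,
  decay_model(duration_min = 62, n_frames = 5),
  noise = noise_model(photon_scale = 40), seed = 1)
intensity_trajectory(series$frames) |> filter(frame == 5)
```

## Numerical choices and edge cases

- **Percentile convention.** Linear interpolation (type 7) everywhere:
  distribution summaries, IQR, and the contrast saturation quantile.
  The display transform `adjust_contrast()` clips at the
  `(1 − f)`-quantile and rescales to [0, 1]; a constant raster has no
  defined rescale and returns zeros with a warning.
- **Storage.** Frames are multi-page TIFFs (page order in a JSON
  sidecar, never guessed from content) with 32-bit integer samples and a
  per-channel `intensity_unit` scale; integer-valued data round-trip
  bit-exactly, arbitrary reals are quantized at 2⁻³² relative. Masks are
  16-bit label TIFFs.
- **Degenerate inputs** fail loudly rather than returning arbitrary
  numbers: constant rasters in the orientation analysis and the
  segmenter, featureless channels in drift estimation, empty value sets
  in summaries. A channel whose t = 0 mean is zero gets `NA` percent
  change with a warning while other channels proceed.
- **Determinism.** Every stochastic generator takes a seed and is
  bit-reproducible; `run_analysis()` records mode, seed, and full
  configuration in each report header, so any report can be regenerated
  byte-identically. The built-in segmenter has no randomized steps.
- **Problem sizes.** The test-suite and validation scenes use rasters of
  roughly 120–200 px and series of 5–13 frames; these sizes give exact
  noise-free recoveries and stable noisy-recovery statistics while
  keeping the whole suite fast, and all analyses scale directly to the
  500–800 px rasters typical of acquisition.

## Known limitations

AR depends on binning (see above) and, through the radial band, on which
spatial scales count as "fiber"; cross-study comparisons need matched
settings. Phase-correlation drift assumes a rigid lateral shift — it
does not model rotation, scaling, or the axial drift that accompanies
tissue relaxation. The redox ratio is a relative, not absolute, metabolic
measure, and no spectral unmixing is attempted. The built-in segmenter is
a fixture-scale tool; densely packed or low-SNR tissue needs the external
segmenter the mask-ingestion path is designed around.
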