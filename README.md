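# nloiquant

Quantitative analysis of label-free multimodal nonlinear optical imaging
(NLOI) data, for researchers working with intraoperative or bench-top
multiphoton microscopes that acquire two- and three-photon
autofluorescence (2PF, 3PF) together with second- and third-harmonic
generation (SHG, THG). Such systems produce co-registered four-channel
rasters of fresh tissue; this package turns them into numbers:

- **Collagen fiber orientation** from the SHG channel by a
  Fourier-domain angular filter: the power spectrum is integrated over
  rotating wedges, yielding an angular energy distribution
  E(θ) on [0°, 180°), the dominant fiber angle, and the **alignment
  ratio** AR = max E / mean E (1 = isotropic network, larger = more
  co-aligned bundles). Spectral energy lies perpendicular to the fibers;
  the 90° mapping is applied internally so all reported angles are fiber
  angles.
- **Metabolic profiling** by the pixel-wise **optical redox ratio**
  ORR = 2PF / (2PF + 3PF) ≈ FAD / (FAD + NAD(P)H), with masked per-cell
  distribution summaries (mean, median, SD, IQR = p75 − p25),
  per-channel intensity profiles, and tie-corrected Kruskal–Wallis group
  comparisons.
- **Longitudinal analysis** of frame series — per-channel percent
  intensity change, whole-frame and segmented ORR trajectories, and
  sub-pixel lateral drift by phase correlation — for tracking tissue
  degradation and drug response over an hour-scale imaging session.
- A **synthetic scene generator** (fibrous SHG textures, cells with
  exact per-cell ORR, lipid droplets, Poisson/Gaussian noise, decay +
  drift + drug-response series) providing ground truth for every
  estimator.

Frames travel as multi-page TIFFs with a JSON sidecar (channel order,
pixel size, time); label masks from external segmenters are ingested as
integer TIFFs and applied identically to all four channels.

## Worked example

Fiber orientation of a synthetic scene of 40 fibers all at 30°:

```r
library(nloiquant)

scene <- generate_fiber_image(
  fiber_scene(image_size_px = 192, pixel_size_um = 0.7, n_fibers = 40,
              orientation = orientation_fixed(30), fiber_length_um = 50,
              seed = 7))
analyze_fibers(scene$shg, pixel_size_um = 0.7)
#> <alignment_result> AR = 26.947, dominant angle = 29 deg (180 wedges)
```

The dominant angle lands within one 1° wedge of the true 30°, and the
AR of ~27 reflects a strongly aligned scene (a flat distribution would
give exactly 1).

Per-cell redox ratios from a synthetic cell scene, via a ground-truth
mask:

```r
sc <- generate_cell_scene(cell_scene(image_size_px = 150, n_cells = 3,
                                     orr_targets = c(0.72, 0.86, 0.94),
                                     total_pf_brightness = 1, seed = 3))
m  <- orr_map(sc$frame)
mk <- segmentation_mask(sc$ground_truth$label_mask, source = "ground_truth")
summarize_distribution(m, mask = mk, label = 1)
#> # A tibble: 1 × 7
#>       n  mean median    sd   p25   p75   iqr
#>   <int> <dbl>  <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1   226  0.72   0.72     0  0.72  0.72     0
```

The noise-free scene reproduces the requested ORR of 0.72 exactly over
all 226 pixels of cell 1. A degradation series with per-channel decay
fractions 25/60/30/65% over 62 minutes, under shot noise at 40 photons
per unit intensity:

```r
series <- simulate_time_series(
  sc$frame, decay_model(duration_min = 62, n_frames = 5),
  noise = noise_model(photon_scale = 40), seed = 1)
intensity_trajectory(series$frames) |> dplyr::filter(frame == 5)
#> # A tibble: 4 × 5
#>   frame time_min channel mean_intensity pct_change
#>   <int>    <dbl> <chr>            <dbl>      <dbl>
#> 1     5       62 2PF            0.0190       -25.0
#> 2     5       62 3PF            0.00196      -59.5
#> 3     5       62 SHG            0             NA
#> 4     5       62 THG            0.207        -65.0
```

The recovered percent changes match the imposed decay to well within the
shot-noise envelope (the cell scene carries no SHG signal, so that
channel's percent change is undefined and flagged `NA`).

A command-line front end wraps the same pipeline:

```sh
exec/nloi simulate --config cfg.json --seed 4 --out out/
exec/nloi fibers   --config cfg.json --out out/
```

Every report records its mode, seed, and configuration, and regenerates
byte-identically from them.

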