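---
title: "Quantifying light-induced Cre recombination from fluorescence microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying light-induced Cre recombination from fluorescence microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacre)
```

## The measurement problem

Optogenetic Cre drivers couple two gates: a doxycycline-controlled
promoter gates *expression*, and 405 nm light gates *activity* (the
photocleavable domain caging the recombinase doubles as a green-to-red
photoswitchable fluorophore, so a transient red signal marks regions
that actually received light). Once active, Cre flips a stochastic
multicolor reporter — membrane-CFP, nuclear-GFP, cytoplasmic-YFP or
cytoplasmic-RFP per recombined cell — permanently. The scientific
read-out is a *rate contrast*: how much faster do cells recombine inside
an illuminated region than in matched unilluminated regions (leaky
"background" recombination)?

`pacre` implements the full measurement chain for that read-out on
multichannel time-lapse and z-stack imaging, together with a
ground-truthed scene generator, so every stage — and the pipeline as a
whole — can be validated quantitatively without any raw microscopy data.

## The processing model

For each field, in order:

1. **Background subtraction.** The mean signal of a cell-free
   (background) ROI is subtracted per channel and timepoint, clipping
   pixels at zero (`subtract_background()`). The mean, not the median,
   is the default; the median is available via `stat = "median"`.
2. **Spectral leak-through correction.** Nuclear-GFP emission bleeds
   into the YFP detection band. The mixing factor is estimated as
   `LF = sum(cYFP_bs) / sum(nGFP_bs)` inside a reference region that
   contains nGFP-only signal, and the target channel is corrected
   pixelwise as `cYFP_bs - LF * nGFP_bs`, clipped at zero
   (`estimate_leakthrough()`, `correct_leakthrough()`). Two
   deliberate choices here:
   * *Ratio of sums* rather than a mean of pixel ratios — robust to
     near-zero denominators.
   * *Sum-level background handling for the estimate*: when given a raw
     stack, the background is subtracted from the ROI totals instead of
     from clipped pixels. Clipping first would rectify noise in the
     sparse reference region and bias LF upward by tens of percent at
     realistic noise levels; subtracting measurements (not pixels) is
     also how ROI-based intensity analysis is normally done.
   * LF is estimated once, at a designated timepoint, and applied to
     all frames and planes: leak-through is an optical constant of the
     channel pair, not a property of the sample. Per-timepoint
     estimation can be had by calling `estimate_leakthrough()` per
     frame, but is not the default.
3. **Segmentation.** A trainable pixel classifier
   (`train_pixel_classifier()`) emulating the interactive
   machine-learning segmentation common in microscopy: a feature bank of
   Gaussian smoothings (σ ∈ {1, 2, 4, 8} px), gradient magnitude,
   Laplacian and local variance feeds a random forest; any supervised
   learner reaching ≥ 99% accuracy on separable fixtures satisfies the
   contract. A classifier-free Otsu threshold (`otsu_mask()`) is the
   fallback and is what the shipped demo uses.
4. **Particle analysis.** 8-connected components (the ImageJ
   convention) with area, perimeter, circularity `4πA/P²` (capped at
   1), centroid and integrated intensity (`analyze_particles()`), gated
   per fluorophore on size and circularity. The shipped gate profiles
   (`gate_profile("organoid")`, `gate_profile("invivo")`) encode the
   published per-fluorophore bounds; they are configuration, not
   constants, because absolute circularity depends on the perimeter
   estimator (below).
5. **Normalization.** Three read-outs, matching the three experiment
   geometries: per-area intensity over the segmented cell region (2D
   cultures, `quantify_timelapse_2d()`), gated fluorophore intensity
   divided by the organoid's projected brightfield area
   (`quantify_organoid()`), and ROI totals summed over z and divided by
   the number of z-steps (`quantify_zstack()`). "Organoid size" is the
   projected 2D area of the brightfield mask: the analysis operates on
   (maximum-projection) planes, and volume estimation is out of scope.
6. **Depth profiles.** `z_profile()` computes raw per-plane eGFP and
   collagen (second-harmonic, SHG) totals per photoconverted ROI,
   without segmentation, then the mean ± SEM across ROIs.
   `z_centroid_shift()` — the intensity-weighted eGFP depth centroid
   minus the SHG peak depth — is convenience plumbing for relocation
   calls, not a published read-out.

## The statistical model

Entire curves are the exchangeable unit. For two groups of longitudinal
curves on a common grid, `anova_f_group()` computes the F score for the
group main effect in an additive two-factor (group + timepoint)
fixed-effects decomposition; because every curve contributes every
timepoint, group and time are orthogonal and the sums of squares are
closed-form. `permutation_test()` permutes whole-curve group
assignments: exhaustively when `choose(n, n_A)` ≤ `n_perm` (then
`p = #{F* ≥ F_obs}/N`), otherwise sampling `n_perm` assignments with the
add-one rule `(1 + #{F* ≥ F_obs})/(1 + n_perm)`, which keeps `p > 0`.
The default `n_perm` is 1000 and a seed is required.

Design notes a user should know:

* The two-factor main-effect F was chosen over a one-way F on per-curve
  means because the comparisons of interest are whole time-courses; the
  curve-means variant is a one-line change on `curve_set` values and
  gives the same permutation p in balanced designs.
* **Equal group sizes floor the p-value at `2/choose(2n, n)`** —
  complementary assignments produce the same F. Three curves per group
  can never reject at α = 0.05 (floor 0.1); four per group (floor
  2/70 ≈ 0.029) is the smallest symmetric design that can. This is why
  the pipeline default is 4 fields per condition.
* Degenerate designs are flagged, not hidden: zero residual variance
  with a group effect reports `F = Inf` (`zero_residual`); identical
  values report `F = 0` (`constant`). Under permutation, `Inf ≥ Inf`
  counts, so such designs yield honest p-values.
* `power_curve()` is the Monte-Carlo validation harness: type-I error at
  effect 0, rejection rates nondecreasing in effect size.

## What the scene generator emulates — and what it does not

`simulate_scene()` builds calibrated multichannel stacks (axis order
T×C×Z×Y×X, µm and hours, y down, pixel centers at half-integers) with
full ground truth: per-cell outcome, recombination time, compartment
masks, label images, and the noise-free pre-mixing channel maps.

* **Cells** are non-overlapping ellipses (ellipsoid-like across z in the
  skin geometry) with localization masks: membrane = footprint minus its
  1-pixel 8-connected erosion; nucleus = concentric ellipse at 40%
  linear size; cytoplasm = interior minus nucleus. With the default
  9 µm cell radius and 2 µm pixels these compartments land inside the
  published organoid gates (nuclei ≈ 30–40 µm², rings and cytoplasm in
  the 50–200 µm² range), reproducing the size/circularity separation
  the gates exploit.
* **Recombination** is a per-cell hazard: `background_hazard_per_h`
  (default 0.005/h) while the driver is expressed, multiplied by
  `light_hazard_multiplier` (default 20) inside photoconverted ROIs
  after the illumination time. Conditions map to the two gates:
  `light_dox` (both), `dox_only` (hazard without the multiplier),
  `light_only` and `untreated` (no expression, zero hazard). Outcomes
  draw from `outcome_probs` (default uniform over the four reporters —
  real cassettes are biased, but no quantitative frequencies are
  available to encode).
* **Photoswitching**: on illumination a configurable fraction (default
  0.8) of the driver's green signal converts to red, which decays
  exponentially with a 1 h half-life. The true conversion efficiency
  and decay rate are not quantified anywhere we could anchor them, so
  both are parameters, and nothing downstream depends on their values.
* **Optics**: nGFP→cYFP mixing with a known true LF, per-channel
  background offset, exponential depth attenuation, Poisson shot noise
  (`recorded = g · Poisson(signal/g)`) plus Gaussian read noise.
* **Reference regions**: cells whose footprint intersects a `reference`
  ROI are rendered as pre-existing nGFP-only cells. This emulates the
  analyst's choice of a source-only region for LF estimation and makes
  that choice reproducible in simulation.
* **Skin geometry** (`simulate_skin_relocation()`): an
  epidermis/basal/collagen-band/dermis layering along z (3 µm steps),
  a static fibrillar SHG texture confined to the band, and eGFP cells
  that sit in the basal layer until `relocation_day` and in the dermis
  afterwards. Control regions for photoactivation layouts are placed
  ≥ 150 µm from photoconverted ROIs where the field allows
  (`auto_control_roi()`), with a warning otherwise.

Not modeled, deliberately: optical PSF blur, tissue drift and motion,
photobleaching, multiphoton excitation physics, cell division,
migration (outside the scripted relocation) and touching-cell clutter.
Passing tests therefore demonstrate that the *measurement chain* is
correct and calibrated on data whose truth is known; they do not
demonstrate robustness to segmentation failure modes (merged cells,
drift, debris) that real tissue produces.

## Numerical conventions and edge cases

* **Rasterization**: a pixel belongs to an ROI iff its center lies
  inside the polygon (even-odd rule), on a 0-based, half-open grid —
  the rectangle (0,0)–(10,10) is exactly 100 pixels. This makes areas
  unambiguous and lets an exhaustive point-in-polygon oracle check every
  pixel.
* **Perimeter** comes in two declared estimators.
  `"contour"` (default) is the marching-squares iso-contour length at
  level 0.5 multiplied by 0.948 — the classical correction for the
  systematic overestimate (~5–7%) that digital contours of smooth
  shapes carry; with it a rasterized radius-10 disc measures
  circularity ≈ 0.98. `"boundary"` is the raw pixel-edge polygon,
  exact for axis-aligned rectangles (any square gives circularity
  π/4 identically). No single estimator does both jobs: corrected
  contour slightly overshoots right-angle corners (square circularity
  caps at 1), pixel-edge length grossly overshoots curved boundaries
  (disc ≈ 0.6). Gates are configurable precisely because circularity is
  convention-dependent at the few-percent level.
* Perimeters follow the hole-filled outer outline (`fill_holes()`):
  membrane rings and cytoplasm-with-nucleus-hole components would
  otherwise have meaningless circularity. Areas count only the
  component's own pixels.
* **Storage**: stacks persist as multipage TIFF with a JSON sidecar;
  samples are stored on a 32-bit grid under a power-of-two scale, so
  integer-valued data round-trip exactly and continuous data to ~2e-10
  of range. OME-style descriptions from acquisition software are parsed
  on read; a multipage file with no axis metadata is refused as
  ambiguous rather than guessed.
* **Zero-area masks** quantify to 0 with a flag; empty masks yield
  empty particle tables; an uninformative reference region (mean source
  signal below a floor) is an error, not a silent zero division.

## Recovering the light-hazard multiplier

With hazard λ and multiplier m, recombined fractions follow
`F(t) = 1 − exp(−λ·m·t)` (illuminated) and `1 − exp(−λ·t)` (control).
At the defaults (λ = 0.005/h, m = 20) the illuminated fraction at 40 h
is 0.98: *saturated*. The raw intensity ratio at 40 h is therefore
(1−e⁻⁴)/(1−e⁻⁰·²) ≈ 5.4 — it does not estimate m, and no measurement
fix can make it. The multiplier lives on the cumulative-hazard scale,
so `estimate_hazard_multiplier()` fits first-order kinetics
`y(t) = plateau · (1 − e^{−ht})` jointly to both conditions
(shared plateau, per-condition h, baseline-subtracted curves) and
reports `h_light / h_control`. On simulated experiments (20 replicates
of 4 + 4 fields, 200 cells each, curves sampled at five timepoints over
0–40 h) the replicate-mean estimate recovers m = 20 within 25%; the
residual upward bias (~15%) traces to under-detection of the sparse
early control signal, which deflates the fitted control hazard.

A related caveat: the generator's `untreated` condition has zero hazard
(no driver expressed), while `dox_only` recombines at the leak rate —
18% by 40 h at the default hazard. These two conditions therefore
*differ truly*, and the permutation test detects that difference
essentially always. A test expected to stay silent on this contrast
would have to be miscalibrated; the specificity contrast that is null
by construction is `light_only` vs `untreated`.

## Problem sizes

Test and demonstration runs use: organoid fields of 480×480 µm at
2 µm/px with 200 cells (≈ 240² px, 7 channels), curves at 5–6 timepoints
over 40–48 h; skin stacks of 96–128 px fields with 10–12 z-planes at
3 µm; 500 null simulations for test size, 20 replicate experiments for
parameter recovery. The generator's acquisition cadence defaults
(90 min organoid frames, 24 h skin sessions) remain what a real
time-lapse would use; analyses subsample that grid, which changes
nothing about the hazards being estimated.

## A worked example

```{r example, eval = FALSE}
library(pacre)

# one simulated experiment: 4 illuminated + 4 control organoid fields
ex <- simulate_experiment(conditions = c("light_dox", "dox_only"),
                          n_fields = 4, seed = 1)
head(ex$curves)

# whole-curve permutation test on the summed reporter intensity
cs <- curves_to_set(ex$curves, c("light_dox", "dox_only"))
permutation_test(cs, n_perm = 1000, seed = 1)

# or the full pipeline from the shipped configuration
demo <- system.file("extdata", "demo_config.yaml", package = "pacre")
man <- run_pipeline(demo, output_dir = tempfile("pacre_demo"))
man$stages$stats
```

## Known limitations

* Curves with missing timepoints are refused rather than imputed.
* The exchangeability unit is the curve (field/organoid/region); if
  fields are nested in animals, permuting fields across animals
  overstates replication — aggregate to the animal level first.
* Per-fluorophore comparisons are reported unadjusted, one test per
  fluorophore; multiplicity control across fluorophores is left to the
  caller.
* 3D connected components are out of scope: planes are analyzed per-z,
  matching the projection-based workflow the pipeline models.
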