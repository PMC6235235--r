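---
title: "Methods: neutrophil quantification for high-throughput light-sheet imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neutrophil quantification for high-throughput light-sheet imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutroscope)
```

## Scope

`neutroscope` implements the computational side of an automated,
fluidic light-sheet fluorescence microscope for larval zebrafish:
specimens travel through tubing into a glass capillary, are registered
along the capillary (anterior–posterior, "x") axis from brightfield
images, and a 3D fluorescence stack of their GFP-expressing neutrophils
is recorded while the capillary is scanned through the light sheet.
The package covers four computations — 3D neutrophil segmentation, 1D
profile registration, PSF estimation from bead stacks, and cohort
statistics — plus seeded synthetic generators that stand in for raw
image data (which, at ~150 GB for a single study, is not
redistributable). Hardware control is out of scope.

## The segmentation pipeline

`segment_stack()` composes five stages, each exported separately:

1. **Coarse threshold** — a deliberately low cutoff; default
   `mean + 3 SD` of the whole stack, which tracks overall specimen
   brightness. Absolute-value and percentile modes exist. All
   thresholds in the package are *strict* (`>`), one convention tested
   at its boundaries.
2. **Morphological cleaning** — closing (dilation then erosion)
   followed by one more erosion, with a 6-connected cross of radius 1
   by default (a cube is available). The mask is treated as embedded in
   an infinite background: it is padded by the radius before the
   operations, because otherwise closing — which must never remove
   foreground — would eat the array faces. Isolated above-threshold
   voxels (shot noise) do not survive the final erosion.
3. **Connected-component labeling** — 26-connectivity by default
   (favouring keeping diffraction-blurred cells whole), labels assigned
   in raster order of each component's first voxel, so labeling is
   deterministic.
4. **Per-object Otsu refinement** — for each object independently, the
   threshold maximizing the between-class variance
   $\omega_0\omega_1(\mu_0-\mu_1)^2$ of its own intensities is found by
   exhaustive search over the observed values; voxels strictly above it
   are kept and the retained voxels are re-labeled globally. This is
   run `otsu_rounds = 2` times ("repeated twice" is read as two total
   executions; three is one parameter away). Objects with a single
   voxel or at most two distinct intensities pass through unchanged —
   there is no bimodality to split. Voxel sets only ever shrink, a
   property the tests assert.
5. **Volume floor** — objects below `min_volume = 3` µm³ (physical
   units: voxel count × dz·dy·dx) are discarded as unphysical.

`count_projection()` applies the same pipeline to the maximum-intensity
projection along z (2D: 8-connectivity, in-plane cross, minimum *area*
2.5 µm² — the cross-section of the 3 µm³ sphere, since no 2D floor is
prescribed anywhere). Because cells behind one another merge in the
projection, this count is provably at most the 3D count; the ratio of
the two quantifies what widefield imaging would miss.

### Default voxel spacing

`(dz, dy, dx) = (2.5, 0.325, 0.325)` µm. The slice pitch is the
instrument's 2.5 µm; the in-plane value is the 666 µm field width
divided by a 2048-pixel sensor — an inference, so it is configurable
everywhere and must be supplied (or present in file metadata) when
reading stacks; it is never silently defaulted.

## Profile registration

A brightfield frame is averaged along y (`profile_from_image`), frames
stepped along the capillary are tiled into a composite
(`tile_composite`, overlaps averaged), and the resulting 1D profile is
matched against a template library (`build_template` /
`template_library`: profiles are normalized to zero mean and unit
variance before averaging, because exposure varies between sessions).

`match_offset()` implements both comparison methods, which agree to
within one sample on clean profiles:

* **crosscorr** — the profile is offset sample-by-sample against the
  template, multiplied and summed over the overlap; the offset is the
  argmax. The per-shift score is the *Pearson correlation within the
  overlap window*. A plain product-sum divided by the overlap length is
  biased for smooth profiles: dropping a few edge samples can outscore
  true alignment whenever the lag-1 autocorrelation exceeds
  $(n-1)/n$, which breaks the identity `match(p, p) = 0`. Re-centering
  within the window bounds the score by 1 and makes zero shift exact.
  Shifts leaving less than 25% of the template overlapping are
  excluded; ties break toward the smaller |offset|.
* **minimum** — the difference between the locations of the two
  intensity minima (the eye/swim-bladder dips are the strong features
  this relies on).

Offsets are integer-sample only: the instrument's 0.3 mm coarse steps
dwarf the ~20 µm precision target, so the profile step — not
interpolation — sets the resolution.

### The closed-loop simulation

`simulate_fine_positioning()` iterates observe → match → move, with the
commanded correction corrupted by Gaussian stage noise; a zero estimate
commands no move (hence no noise) and stops the loop. The synthetic
template is sampled at **10 µm** by default: anatomical features are
hundreds of µm wide, and the step must be comparable to the stage noise
for the loop to settle — with a 3 µm step and 10 µm stage noise the
probability of landing within one sample per iteration is only ~0.24,
so no realistic iteration budget reaches a sub-sample residual, whereas
at 10 µm sampling the loop converges in 1–3 iterations. This choice was
made from that analysis, not tuned on test outcomes. The simulation is
a property stand-in for the instrument's measured ~20 µm repeatability,
which requires the physical hardware.

## PSF estimation

`estimate_psf()` locates the bead (smoothed argmax, raster-first tie
break), refuses beads at stack faces (truncated profiles), extracts
single-voxel line scans along x, y and z, and fits
$A e^{-(u-u_0)^2/2\sigma^2} + B$ to each with `nls`
(`scaleOffset` handles exact zero-residual data; a Nelder–Mead fallback
guards non-convergence). Initialization is derivative-free: amplitude
`max − min`, baseline `min`, center at the maximum, σ from the
half-width at half-maximum divided by 1.177. **Reported widths are
Gaussian standard deviations, not FWHM** (multiply by 2.355); the
instrument's nominal values are σ ≈ 0.6 µm in-plane and σ ≈ 3.4 µm
along the detection axis, the latter reflecting the sheet thickness.

## Cohort statistics

Per-fish records carry a neutrophil count, optional total fluorescence,
group label and optional anterior–posterior positions. All SDs are
sample SDs (n−1); a single-fish group flags its SD undefined rather
than reporting 0. `regress_intensity_on_count()` is OLS with intercept;
`ap_histogram()` uses half-open 50 µm bins by default over the 666 µm
field. `compare_groups()` reports the fold change of means with
first-order propagation of the two SEMs,
$\Delta f = f\sqrt{(s_t/\bar x_t)^2 + (s_c/\bar x_c)^2}$, plus a seeded
bootstrap interval as a cross-check — applied to printed group
summaries of 95.1 ± 23.4 (N = 21) vs 114.2 ± 38.1 (N = 19) this
propagation gives 1.20 ± 0.11, matching the reported ±0.1.
`projection_ratio()` averages per-fish 2D/3D count ratios, excluding
(and reporting) zero-denominator fish.

## Synthetic data: what it emulates, and what it does not

Cells are **anisotropic Gaussian intensity blobs**, not hard
ellipsoids: a diffraction-blurred cell has no sharp edge, and a hard
shape would make per-object Otsu refinement trivial. Convolving a
Gaussian blob with the Gaussian PSF is again Gaussian —
$\sigma_\mathrm{eff} = \sqrt{r^2 + \sigma_\mathrm{psf}^2}$ per axis,
peak reduced by $\prod r/\sigma_\mathrm{eff}$ — so stacks are rendered
in closed form. This makes the mass-conservation invariant exact to
numerical precision and generation fast, at the price of not modelling
asymmetric aberrations. Blobs must sit ≥ 3 post-blur σ from every face
(truncation would corrupt conservation and recovery tests).

Noise is Poisson with gain 1 by default (Gaussian available for
analytic work). **SNR is peak-referred**: the post-blur peak amplitude
divided by the noise SD *at the peak* (`snr_amplitude()`), the same
convention as for bead stacks. Referring SNR to the background SD
instead quietly lowers the effective peak SNR by √(1+amp/bg) under
Poisson statistics, and at a nominal "SNR 10" that difference is what
separates reliable exact recovery from occasional just-above-floor
Otsu fragments.

Default cohort parameters state the study's world: mean count 90 with
SD/mean = 0.30 (negative binomial; the observed inter-individual
variation is far beyond Poisson), and per-cell lognormal intensities
with CV 3.49 — the value at which the closed-form R² of the
count-mixture model,
$R^2 = \mathrm{var}(N)/(\mathrm{var}(N) + \bar N \cdot cv^2)$,
equals the observed 0.4. That CV folds *all* brightness variability
(per-cell expression, depth attenuation, specimen orientation) into one
per-cell term; it is not a claim about single-cell biochemistry.

One density caveat: the global `mean + 3 SD` threshold assumes signal
occupies a small fraction of the image. That holds in 3D (bright cells
fill well under 1% of a stack) and on the instrument's real ~666 × 431
µm projections (~2% of the area), but a synthetic stack that crams
cells into a tiny xy field can push the projected signal fraction past
~15%, at which point the MIP threshold is signal-dominated and the 2D
count collapses. Projection tests therefore use fields with realistic
projected density; percentile thresholds are available where denser
scenes are wanted.

What a green test does **not** establish: the generators contain no
anatomy (no gut autofluorescence structure, no specimen rotation, no
touching cells — cell splitting is explicitly out of scope), so
recovery rates here bound the pipeline's behaviour on well-separated
bright cells only. Supplementary-style tables produced by
`synthetic_group_from_summary()` are sampled from printed summary
statistics and are labelled synthetic; they exercise the machinery but
cannot re-derive the study's raw data values.

## Numerical choices and degenerate inputs

* Otsu candidates are the observed intensities minus the maximum (the
  upper class is never empty); ties take the smallest threshold.
* Empty masks, blank stacks, all-filtered label sets and empty AP
  position lists all return empty-but-well-formed results, never
  errors; genuinely undefined quantities (SD of one fish, fold over a
  zero-mean control, Otsu of a constant object) are flagged or errored
  explicitly.
* TIFF support is a minimal baseline implementation (uncompressed
  grayscale, uint8/16/float32, one strip per page) written because no
  TIFF package is assumed; spacing travels as ImageJ-style metadata
  (`XResolution`/`YResolution` as pixels-per-micron rationals,
  `spacing=` in the description) and is verified against Python
  `tifffile` in the test suite. Reading a file with no spacing metadata
  and no override is an error by design.
* All file writes go through a write-temp-then-rename helper, so
  readers never observe partial files.

## Known limitations

Touching or overlapping cells are not split (no watershed); the
projection counter inherits this. The PSF fit is axis-aligned 1D, not a
full 3D Gaussian. The correlation search is integer-sample. The
brightfield generator models dips on a flat baseline, not full
absorption images. These mirror the scope of the instrument's own
processing rather than gaps to be filled.
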