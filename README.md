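# neutroscope

Computational toolkit for automated high-throughput light-sheet
fluorescence microscopy of larval zebrafish. In the instrument this
package serves, anaesthetized larvae flow through tubing into a square
glass capillary, are registered along the capillary axis from
brightfield images, and a 3D fluorescence stack of their
GFP-expressing neutrophils (≈ 0.3 mm³ per fish) is recorded while the
capillary is scanned through a vertical light sheet. `neutroscope`
implements everything downstream of the camera, for microscopists and
quantitative biologists who need cell counts and distributions from
such stacks:

* **3D neutrophil segmentation** — coarse threshold (default
  mean + 3 SD), morphological closing + erosion (radius 1), connected
  components, per-object Otsu refinement iterated twice (each object is
  re-thresholded at the cutoff maximizing its own between-class
  variance ω₀ω₁(μ₀−μ₁)², then re-labeled), and a 3 µm³ physical volume
  floor. Also the 2D maximum-intensity-projection counterpart, whose
  count is provably ≤ the 3D count (occluded cells merge).
* **Specimen positioning** — 1D brightfield intensity profiles
  (frames averaged along y, tiled composites), template libraries, and
  offset estimation by cross-correlation or by intensity-minimum
  location, plus a closed-loop fine-positioning simulator.
* **PSF estimation** — Gaussian fits A·exp(−(u−u₀)²/2σ²)+B to line
  scans through a fluorescent bead; widths are reported as Gaussian σ
  (not FWHM). Nominal instrument values: σ ≈ 0.6 µm in-plane, ≈ 3.4 µm
  along the detection axis.
* **Cohort statistics** — per-fish count summaries (sample SD),
  intensity-on-count OLS regression with R², pooled anterior-posterior
  histograms, group fold changes with propagated and bootstrap
  uncertainties, and 2D/3D count ratios.
* **Synthetic data** — seeded generators for blob stacks with ground
  truth, bead stacks, brightfield profiles and cohort tables, so every
  stage is testable with no raw data. Deterministic given recipe + seed.
* **I/O and CLI** — a minimal multi-page TIFF reader/writer carrying
  voxel spacing (ImageJ-style metadata, interoperable with `tifffile`),
  supplementary-table readers, profile/config CSVs, and a thin
  command-line interface (`inst/cli/neutroscope.R`) with `simulate`,
  `segment`, `project-count`, `position`, `psf`, `analyze` and
  `pipeline` subcommands.

## Worked example

Simulate a stack of 8 well-separated synthetic neutrophils (Gaussian
blobs blurred by the instrument's PSF over Poisson background) and
segment it:

```r
library(neutroscope)

spacing <- c(2.5, 0.325, 0.325)            # (dz, dy, dx) um
shape   <- c(48L, 160L, 320L)              # ~104 x 52 x 118 um (x, y, z)
ext     <- rev((shape - 1) * spacing)
centers <- place_separated_centers(8, ext, c(10.5, 10.5, 14), 24, seed = 11)
amp     <- snr_amplitude(15, background = 100)   # peak SNR 15, Poisson
blobs   <- lapply(1:8, function(i)
  blob_spec(centers[i, ], radii = c(3, 3, 3),
            peak_intensity = peak_for_amplitude(amp, c(3, 3, 3))))
st  <- make_neutrophil_stack(stack_recipe(shape = shape,
                                          voxel_spacing = spacing,
                                          blobs = blobs, seed = 11))
seg <- segment_stack(st$grid, seg_params())
seg
#> <neutro_seg> 8 objects (coarse threshold 159.248)
#>   above_threshold_voxels   31923
#>   coarse_objects           11
#>   refined_objects          32
#>   final_objects            8
head(seg$objects[, 1:7], 3)
#>   label voxels volume_um3 total_intensity     x_um     y_um     z_um
#> 1     1    300   79.21875          106842 11.63909 12.52953 99.41591
#> 2     2    312   82.38750          110820 23.57060 25.26032 32.31005
#> 3     3    283   74.72969          101485 27.27276 35.42510 71.53781
```

All 8 planted cells are recovered; the run log shows the coarse stage
found 11 candidate objects (noise clusters included) and the Otsu
rounds plus the 3 µm³ floor left exactly the 8 real ones. Counting the
same stack from its 2D projection merges two cells that overlap in
(x, y):

```r
count_projection(st$grid)
#> [1] 7
```

Registration, PSF and cohort statistics:

```r
tpl <- make_brightfield_profile(profile_recipe())      # template, 10 um/sample
obs <- make_brightfield_profile(profile_recipe(offset = 210,
                                               noise_sigma = 20, seed = 4))
match_offset(obs, tpl, "crosscorr", max_shift = 1000)
#> <offset_result> offset +210 um (method crosscorr, score 0.9940)

estimate_psf(make_bead_stack(c(0.6, 0.6, 3.4), snr = 20, seed = 2))
#> <psf_estimate> sigma (x, y, z) = (0.61, 0.62, 3.27) um  [Gaussian SD, not FWHM]
#>   axial/lateral ratio 5.37; residual rms (x,y,z) = (47.6, 47.2, 50.2)

rec <- make_cohort_tables(1000, seed = 14)   # counts ~ NB(90, SD/mean 0.30)
summarize_counts(rec)
#> 89.1 +/- 27.4 neutrophils (mean +/- SD, N = 1000); SD/mean = 0.31
regress_intensity_on_count(rec)
#> intensity ~ count: slope 971.7, intercept 1125, R^2 = 0.422 (N = 1000)
```

The planted +210 µm displacement is recovered exactly despite noise;
the bead round-trip returns the true PSF widths within a few percent;
and the default cohort model reproduces the hallmark statistics of the
biology — inter-individual count variation of ~30% of the mean, and a
total-fluorescence/count correlation weak enough (R² ≈ 0.4) that bulk
brightness is a poor proxy for cell number.

See `vignettes/neutroscope-methods.Rmd` for the models, parameter
choices and limitations.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's headline quantities from scratch against the
installed package — ground-truth recovery on seeded synthetic cohorts
(20 planted cells per stack), planted-shift registration accuracy at 5%
profile noise, the PSF bead round-trip at SNR 20, and cohort summary
statistics on synthetic tables — logging each result and writing the
JSON report to `--out`. All randomness derives from `--seed`.
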