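# Shared builder for the ground-truth recovery cohorts: 20 well-separated
# Gaussian "cells" (radius 3 um, the scale of a neutrophil) over Poisson
# background at the instrument's voxel spacing, with optional planted
# sub-resolution speckles. SNR is peak-referred (see snr_amplitude).
make_recovery_cohort <- function(seed, snr = 10, n_blobs = 20,
                                 speckles = 0) {
  spacing <- c(2.5, 0.325, 0.325)
  shape <- c(48L, 192L, 192L)
  ext <- rev((shape - 1) * spacing)
  n_tot <- n_blobs + speckles
  centers <- place_separated_centers(n_tot, ext, margin_xyz = c(10.5, 10.5, 14),
                                     min_separation = 20, seed = seed,
                                     max_tries = 200000L)
  amp <- snr_amplitude(snr, background = 100, noise_model = "poisson")
  blobs <- lapply(seq_len(n_blobs), function(i)
    blob_spec(centers[i, ], radii = c(3, 3, 3),
              peak_intensity = peak_for_amplitude(amp, c(3, 3, 3))))
  if (speckles > 0) {
    spk <- lapply(n_blobs + seq_len(speckles), function(i)
      blob_spec(centers[i, ], radii = c(0.2, 0.2, 0.2),
                peak_intensity = peak_for_amplitude(1.5 * amp, c(0.2, 0.2, 0.2))))
    blobs <- c(blobs, spk)
  }
  st <- make_neutrophil_stack(stack_recipe(
    shape = shape, voxel_spacing = spacing, blobs = blobs,
    noise_model = "poisson", seed = seed))
  list(grid = st$grid, centers = centers[seq_len(n_blobs), , drop = FALSE],
       speckle_centers = if (speckles > 0)
         centers[n_blobs + seq_len(speckles), , drop = FALSE])
}
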