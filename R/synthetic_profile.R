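# Synthetic 1D brightfield profiles: a bright baseline with Gaussian
# absorption dips standing in for the strong anatomical features (eyes,
# swim bladder) that anchor registration of a larval zebrafish along the
# capillary axis.

#' Recipe for a synthetic brightfield intensity profile
#'
#' @param length number of samples.
#' @param step um per sample (default 10: anatomical features are
#'   hundreds of um wide, so mm-scale registration does not need
#'   sub-micron sampling).
#' @param feature_positions dip centres, um from sample 0.
#' @param feature_depths fractional dips in `(0, 1]` (1 = fully dark).
#' @param feature_widths Gaussian widths of the dips, um.
#' @param baseline bright-field background intensity, units.
#' @param noise_sigma additive Gaussian noise SD, units.
#' @param offset um shift applied to the whole specimen (positive =
#'   displaced toward +x).
#' @param seed integer seed for the noise.
#' @return a `profile_recipe` list.
#' @export
profile_recipe <- function(length = 450L, step = 10,
                           feature_positions = c(600, 2600, 3100),
                           feature_depths = c(0.65, 0.45, 0.30),
                           feature_widths = c(150, 180, 120),
                           baseline = 1000, noise_sigma = 0,
                           offset = 0, seed = 1L) {
  length <- as.integer(length)
  if (length < 2L) stop("'length' must be >= 2 samples")
  stopifnot_scalar_pos(step, "step")
  k <- base::length(feature_positions)
  if (base::length(feature_depths) != k || base::length(feature_widths) != k)
    stop("feature positions, depths and widths must have equal length")
  if (any(feature_depths <= 0) || any(feature_depths > 1))
    stop("'feature_depths' must lie in (0, 1]")
  if (any(feature_widths <= 0)) stop("'feature_widths' must be positive")
  extent <- length * step
  if (any(feature_positions < 0 | feature_positions >= extent))
    stop("feature positions must lie in [0, length*step)")
  structure(list(length = length, step = step,
                 feature_positions = as.numeric(feature_positions),
                 feature_depths = as.numeric(feature_depths),
                 feature_widths = as.numeric(feature_widths),
                 baseline = baseline, noise_sigma = noise_sigma,
                 offset = offset, seed = as.integer(seed)),
            class = "profile_recipe")
}

#' Generate a synthetic brightfield profile
#'
#' Evaluates `baseline * (1 - sum of Gaussian dips)` at the sample
#' positions, with the specimen displaced by `recipe$offset` (the dips
#' are analytic, so fractional offsets are exact), then adds seeded
#' Gaussian noise.
#'
#' @param recipe a [profile_recipe()].
#' @return an [intensity_profile()].
#' @export
make_brightfield_profile <- function(recipe) {
  stopifnot(inherits(recipe, "profile_recipe"))
  u <- (seq_len(recipe$length) - 1) * recipe$step
  v <- rep(1, recipe$length)
  for (j in seq_along(recipe$feature_positions)) {
    c_j <- recipe$feature_positions[j] + recipe$offset
    v <- v - recipe$feature_depths[j] *
      exp(-0.5 * ((u - c_j) / recipe$feature_widths[j])^2)
  }
  v <- recipe$baseline * v
  if (recipe$noise_sigma > 0)
    v <- with_seed(recipe$seed,
                   v + rnorm(length(v), 0, recipe$noise_sigma))
  intensity_profile(v, step = recipe$step)
}
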