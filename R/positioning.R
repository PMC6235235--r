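# Image-based fine positioning along the capillary (x) axis.
#
# The instrument walks the specimen in ~0.3 mm steps, captures a
# brightfield frame at each stop, tiles the frames into one composite,
# averages it along y into a 1D intensity profile, and registers that
# profile against a previously assembled template library. Two
# registration methods are implemented: (i) the peak of the (normalized,
# overlap-only) cross-correlation and (ii) the difference between the
# intensity-minimum locations. On clean single-minimum profiles the two
# agree to within one sample.

#' 1D axial brightfield intensity profile
#'
#' @param values numeric intensities, one per sample along x.
#' @param step um per sample.
#' @param origin physical position of sample 0, um.
#' @return an `intensity_profile`.
#' @export
intensity_profile <- function(values, step, origin = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("a profile needs at least 2 samples")
  if (any(!is.finite(values))) stop("profile intensities must be finite")
  stopifnot_scalar_pos(step, "step")
  structure(list(values = values, step = as.numeric(step),
                 origin = as.numeric(origin)),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> %d samples, step %g um (extent %.0f um)\n",
              length(x$values), x$step, length(x$values) * x$step))
  invisible(x)
}

#' @export
plot.intensity_profile <- function(x, ...) {
  u <- x$origin + (seq_along(x$values) - 1) * x$step
  plot(u, x$values, type = "l", xlab = "x (um)", ylab = "intensity", ...)
  invisible(x)
}

#' Average a brightfield frame along y into a profile
#'
#' @param frame numeric matrix, rows = y, columns = x.
#' @param pixel_um pixel pitch along x, um.
#' @return an [intensity_profile()] of the per-column means.
#' @export
profile_from_image <- function(frame, pixel_um) {
  if (!is.matrix(frame) || !is.numeric(frame) || length(frame) == 0L)
    stop("'frame' must be a non-empty numeric matrix (y rows, x columns)")
  intensity_profile(colMeans(frame), step = pixel_um)
}

#' Tile brightfield frames into one composite image
#'
#' Frames are placed at their nominal stage positions
#' (`0, step, 2*step, ...` um); pixels covered by several frames are
#' averaged.
#'
#' @param frames list of numeric matrices with equal heights.
#' @param step_um stage step between consecutive frames, um.
#' @param pixel_um pixel pitch, um.
#' @return numeric matrix of width `(n-1)*step/pixel + frame width`.
#' @export
tile_composite <- function(frames, step_um, pixel_um) {
  if (!length(frames)) stop("'frames' must be a non-empty list")
  hs <- vapply(frames, nrow, 1L)
  ws <- vapply(frames, ncol, 1L)
  if (length(unique(hs)) != 1L) stop("frames have inconsistent heights")
  step_px <- round(step_um / pixel_um)
  if (length(frames) > 1L && step_px < 1L)
    stop("'step_um' must be at least one pixel")
  total_w <- (length(frames) - 1L) * step_px + ws[length(ws)]
  acc <- matrix(0, hs[1], total_w)
  cnt <- matrix(0, hs[1], total_w)
  for (i in seq_along(frames)) {
    cols <- (i - 1L) * step_px + seq_len(ws[i])
    if (max(cols) > total_w) stop("frame ", i, " extends past the composite")
    acc[, cols] <- acc[, cols] + frames[[i]]
    cnt[, cols] <- cnt[, cols] + 1
  }
  if (any(cnt == 0)) stop("gap in composite: step exceeds frame width")
  acc / cnt
}

# zero-mean, unit-variance; constant profiles map to all zeros
normalize_values <- function(v) {
  s <- sd(v)
  if (!is.finite(s) || s == 0) return(rep(0, length(v)))
  (v - mean(v)) / s
}

#' Average profiles into a library template
#'
#' Each profile is normalized to zero mean and unit variance (brightfield
#' exposure varies between sessions) and the normalized profiles are
#' averaged pointwise.
#'
#' @param profiles list of [intensity_profile()]s with equal length and step.
#' @return an [intensity_profile()] template.
#' @export
build_template <- function(profiles) {
  if (!length(profiles)) stop("'profiles' must be non-empty")
  stopifnot(all(vapply(profiles, inherits, TRUE, "intensity_profile")))
  steps <- vapply(profiles, `[[`, numeric(1), "step")
  lens <- vapply(profiles, function(p) length(p$values), 1L)
  if (length(unique(steps)) != 1L) stop("profiles have mixed steps")
  if (length(unique(lens)) != 1L) stop("profiles have mixed lengths")
  m <- rowMeans(vapply(profiles, function(p) normalize_values(p$values),
                       numeric(lens[1])))
  intensity_profile(m, step = steps[1])
}

#' A named library of registration templates
#'
#' @param templates named list of [intensity_profile()]s sharing one step.
#' @return a `template_library`.
#' @export
template_library <- function(templates) {
  if (!length(templates)) stop("library must contain at least one template")
  if (is.null(names(templates)) || any(names(templates) == ""))
    stop("templates must be named")
  stopifnot(all(vapply(templates, inherits, TRUE, "intensity_profile")))
  steps <- vapply(templates, `[[`, numeric(1), "step")
  if (length(unique(steps)) != 1L) stop("templates have mixed steps")
  structure(list(templates = templates), class = "template_library")
}

# Correlation score over integer shifts; returns best k and score.
# The score at shift k is the Pearson correlation of the two profiles
# restricted to their overlap. Re-centering within each overlap window
# (rather than dividing a global product sum by the overlap length)
# keeps the score in [-1, 1]: for smooth profiles the raw overlap-mean
# formulation scores a one-sample shift above the true zero shift,
# because dropping edge samples outweighs the slight misalignment.
crosscorr_best <- function(p, q, max_k, min_overlap) {
  n <- length(p); m <- length(q)
  ks <- -max_k:max_k
  scores <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    # overlap of p(i) with q(i - k)
    lo <- max(1L, 1L + k); hi <- min(n, m + k)
    ov <- hi - lo + 1L
    if (ov < min_overlap) next
    ps <- p[lo:hi]; qs <- q[(lo:hi) - k]
    pc <- ps - mean(ps); qc <- qs - mean(qs)
    den <- sqrt(sum(pc^2) * sum(qc^2))
    if (den == 0) next
    scores[i] <- sum(pc * qc) / den
  }
  if (all(is.na(scores))) stop("no shift leaves sufficient profile overlap")
  best <- max(scores, na.rm = TRUE)
  cand <- ks[!is.na(scores) & scores >= best - 1e-12]
  k <- cand[which.min(abs(cand))]          # tie toward smaller |offset|
  list(k = k, score = best)
}

#' Offset between a profile and a template
#'
#' Method `"crosscorr"`: the profile is offset sample-by-sample against
#' the template, multiplied and summed over the overlap; the score at
#' each shift is the Pearson correlation within the overlap window (so
#' edge truncation cannot outscore true alignment) and the offset is the
#' argmax over every integer-sample shift with `|k*step| <= max_shift`.
#' Shifts leaving less than `min_overlap_frac` of
#' the template overlapping are excluded. Method `"minimum"`: the offset
#' is the difference between the two intensity-minimum locations. Ties
#' break toward the smaller |offset|.
#'
#' @param profile an [intensity_profile()] measured from the specimen.
#' @param template an [intensity_profile()] or [template_library()]; with
#'   a library, the template with the best peak normalized correlation
#'   wins.
#' @param method `"crosscorr"` or `"minimum"`.
#' @param max_shift search half-range, um.
#' @param min_overlap_frac minimum usable overlap as a fraction of the
#'   template length (default 0.25).
#' @return an `offset_result` with `offset` (um, positive = specimen
#'   displaced toward +x), `score`, `method`, `best_template`.
#' @examples
#' t <- make_brightfield_profile(profile_recipe(noise_sigma = 0))
#' p <- make_brightfield_profile(profile_recipe(noise_sigma = 0, offset = 210))
#' match_offset(p, t, method = "crosscorr", max_shift = 1000)$offset
#' @export
match_offset <- function(profile, template,
                         method = c("crosscorr", "minimum"),
                         max_shift = 1500, min_overlap_frac = 0.25) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "intensity_profile"))
  if (inherits(template, "template_library")) {
    res <- lapply(names(template$templates), function(nm) {
      r <- match_offset(profile, template$templates[[nm]], method = method,
                        max_shift = max_shift,
                        min_overlap_frac = min_overlap_frac)
      r$best_template <- nm
      r
    })
    scores <- vapply(res, `[[`, numeric(1), "score")
    return(res[[which.max(scores)]])
  }
  stopifnot(inherits(template, "intensity_profile"))
  if (abs(profile$step - template$step) > 1e-9)
    stop("profile and template steps differ")
  step <- profile$step
  if (max_shift > length(profile$values) * step)
    stop("'max_shift' exceeds the profile extent")
  max_k <- floor(max_shift / step)
  p <- normalize_values(profile$values)
  q <- normalize_values(template$values)
  min_ov <- max(2L, ceiling(min_overlap_frac * length(q)))
  cc <- crosscorr_best(p, q, max_k, min_ov)
  if (method == "crosscorr") {
    offset <- cc$k * step
  } else {
    offset <- (which.min(profile$values) - which.min(template$values)) * step
  }
  structure(list(offset = offset, score = cc$score, method = method,
                 best_template = NA_character_),
            class = "offset_result")
}

#' @export
print.offset_result <- function(x, ...) {
  cat(sprintf("<offset_result> offset %+g um (method %s, score %.4f%s)\n",
              x$offset, x$method, x$score,
              if (is.na(x$best_template)) ""
              else paste0(", template ", x$best_template)))
  invisible(x)
}

# shift a sampled profile by d_um (linear interpolation, replicate edges)
shift_profile <- function(profile, d_um) {
  n <- length(profile$values)
  u <- (seq_len(n) - 1) * profile$step
  v <- approx(u, profile$values, xout = u - d_um, rule = 2)$y
  intensity_profile(v, step = profile$step, origin = profile$origin)
}

#' Simulate the closed-loop fine-positioning procedure
#'
#' Repeats the instrument's loop: observe a brightfield profile of the
#' specimen at its current residual displacement (the template shifted by
#' the residual, plus profile noise), estimate the offset, and command
#' the corrective stage move, which is corrupted by Gaussian stage noise.
#' If the estimated offset is zero no move is commanded (and no stage
#' noise incurred) and the loop stops.
#'
#' @param template an [intensity_profile()] of the correctly positioned
#'   specimen class.
#' @param true_offset initial displacement, um.
#' @param stage_noise_sd SD of the stage-move error, um.
#' @param profile_noise_sd additive intensity noise SD on each observed
#'   profile, units.
#' @param max_iter maximum corrective iterations, `>= 1`.
#' @param method registration method, see [match_offset()].
#' @param max_shift search half-range, um; defaults to half the template
#'   extent.
#' @param seed integer seed.
#' @return data.frame with one row per executed iteration: `iteration`,
#'   `estimated_offset`, `residual` (um, after the move); attribute
#'   `converged` is `TRUE` when the loop stopped on a zero estimate.
#' @export
simulate_fine_positioning <- function(template, true_offset,
                                      stage_noise_sd = 0,
                                      profile_noise_sd = 0,
                                      max_iter = 5L,
                                      method = "crosscorr",
                                      max_shift = NULL, seed = 1L) {
  stopifnot(inherits(template, "intensity_profile"))
  if (max_iter < 1L) stop("'max_iter' must be >= 1")
  if (is.null(max_shift))
    max_shift <- length(template$values) * template$step / 2
  with_seed(seed, {
    residual <- true_offset
    rows <- list()
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      obs <- shift_profile(template, residual)
      if (profile_noise_sd > 0)
        obs$values <- obs$values + rnorm(length(obs$values), 0, profile_noise_sd)
      est <- match_offset(obs, template, method = method,
                          max_shift = max_shift)$offset
      if (est == 0) {
        rows[[it]] <- data.frame(iteration = it, estimated_offset = 0,
                                 residual = residual)
        converged <- TRUE
        break
      }
      move_err <- if (stage_noise_sd > 0) rnorm(1, 0, stage_noise_sd) else 0
      residual <- residual - est + move_err
      rows[[it]] <- data.frame(iteration = it, estimated_offset = est,
                               residual = residual)
    }
    out <- do.call(rbind, rows)
    attr(out, "converged") <- converged
    out
  })
}
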