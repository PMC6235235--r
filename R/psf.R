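# Point-spread-function estimation from bead stacks.
#
# The optical resolution of the instrument is characterized by imaging
# sub-resolution fluorescent microspheres and fitting a Gaussian to
# axis-aligned line scans through the bead: the in-plane width reports
# the diffraction limit (~0.6 um) and the detection-axis (z) width the
# light-sheet thickness (~3.4 um). Throughout, "width" means the
# Gaussian standard deviation sigma, NOT the FWHM (multiply by 2.355
# for FWHM).

#' Locate the bead in a calibration stack
#'
#' Global intensity maximum after light Gaussian smoothing (sigma 1
#' voxel); ties break to the first voxel in raster order.
#'
#' @param grid a [voxel_grid()].
#' @param smooth_sigma_vox smoothing sigma in voxels (0 disables).
#' @return integer vector `(iz, iy, ix)` of 0-based voxel indices.
#' @export
locate_bead <- function(grid, smooth_sigma_vox = 1) {
  stopifnot(inherits(grid, "voxel_grid"))
  a <- grid$data
  if (max(a) == min(a)) stop("stack is flat: no bead found")
  if (smooth_sigma_vox > 0)
    a <- smooth_gaussian_vox(a, rep(smooth_sigma_vox, 3))
  i <- which.max(a)                         # first max in raster order
  d <- dim(a)
  iz <- (i - 1L) %% d[1]
  rest <- (i - 1L) %/% d[1]
  c(iz, rest %% d[2], rest %/% d[2])
}

#' Fit a 1D Gaussian profile
#'
#' Least-squares fit of `A * exp(-(u - u0)^2 / (2 sigma^2)) + B` to a
#' sampled line. Initialization: `A = max - min`, `B = min`, `u0` at the
#' maximum, `sigma` from the half-width at half-maximum (HWHM / 1.177).
#' Fitting uses `nls` (with `scaleOffset` so exact, zero-residual data
#' converge) with a Nelder-Mead fallback.
#'
#' @param line numeric vector, at least 5 samples, non-constant.
#' @param step um per sample.
#' @return object of class `gauss_fit`: list with `sigma`, `center`,
#'   `amplitude`, `baseline` (um / intensity units), `residual_rms`, and
#'   the data (`u`, `values`, `fitted`).
#' @examples
#' u <- seq(0, 30, by = 0.5)
#' fit <- fit_gaussian_profile(50 + 800 * exp(-(u - 15)^2 / (2 * 3.4^2)), 0.5)
#' fit$sigma
#' @export
fit_gaussian_profile <- function(line, step) {
  line <- as.numeric(line)
  if (length(line) < 5L) stop("need at least 5 samples to fit a Gaussian")
  if (max(line) == min(line)) stop("constant line: nothing to fit")
  stopifnot_scalar_pos(step, "step")
  u <- (seq_along(line) - 1) * step
  B0 <- min(line)
  A0 <- max(line) - B0
  u0 <- u[which.max(line)]
  half <- B0 + A0 / 2
  above <- which(line > half)
  hwhm <- max(step, (max(u[above]) - min(u[above])) / 2)
  s0 <- max(hwhm / 1.177, step / 2)
  df <- data.frame(u = u, y = line)
  fit <- tryCatch(
    nls(y ~ A * exp(-(u - u0)^2 / (2 * s^2)) + B, data = df,
        start = list(A = A0, u0 = u0, s = s0, B = B0),
        control = nls.control(maxiter = 200, scaleOffset = 1,
                              minFactor = 1e-12)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    sse <- function(p) {
      r <- df$y - (p[1] * exp(-(df$u - p[2])^2 / (2 * p[3]^2)) + p[4])
      sum(r^2)
    }
    op <- optim(c(A0, u0, s0, B0), sse, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-14))
    if (op$convergence != 0)
      stop("Gaussian fit failed to converge (nls: ",
           conditionMessage(fit), "; optim code ", op$convergence, ")")
    p <- op$par
    fitted <- p[1] * exp(-(df$u - p[2])^2 / (2 * p[3]^2)) + p[4]
    out <- list(sigma = abs(p[3]), center = p[2], amplitude = p[1],
                baseline = p[4],
                residual_rms = sqrt(mean((df$y - fitted)^2)),
                u = u, values = line, fitted = fitted)
  } else {
    p <- coef(fit)
    fitted <- as.numeric(predict(fit))
    out <- list(sigma = abs(unname(p["s"])), center = unname(p["u0"]),
                amplitude = unname(p["A"]), baseline = unname(p["B"]),
                residual_rms = sqrt(mean((line - fitted)^2)),
                u = u, values = line, fitted = fitted)
  }
  structure(out, class = "gauss_fit")
}

#' @export
print.gauss_fit <- function(x, ...) {
  cat(sprintf("<gauss_fit> sigma %.4g um, center %.4g um, amplitude %.4g, baseline %.4g (residual rms %.3g)\n",
              x$sigma, x$center, x$amplitude, x$baseline, x$residual_rms))
  invisible(x)
}

#' @export
coef.gauss_fit <- function(object, ...) {
  c(sigma = object$sigma, center = object$center,
    amplitude = object$amplitude, baseline = object$baseline)
}

#' @export
plot.gauss_fit <- function(x, ...) {
  plot(x$u, x$values, xlab = "position (um)", ylab = "intensity", ...)
  lines(x$u, x$fitted, col = 2)
  invisible(x)
}

#' Estimate the PSF from a bead stack
#'
#' Locates the bead, extracts axis-aligned line scans through it along
#' x, y and z (single voxel wide by default), and fits a Gaussian to
#' each. The z width reports the light-sheet thickness.
#'
#' @param grid a [voxel_grid()] containing one bead.
#' @param average_halfwidth half-width (voxels) of the perpendicular
#'   averaging window around the line scan; 0 (default) = single-voxel
#'   line.
#' @param min_margin_vox error if the bead sits within this many voxels
#'   of a stack face (truncated profile), default 4.
#' @return object of class `psf_estimate`: `sigma` named `(x, y, z)` in
#'   um, `center_um` `(x, y, z)`, per-axis `fits` (class `gauss_fit`),
#'   `residual_rms`.
#' @examples
#' bead <- make_bead_stack(sigma = c(0.6, 0.6, 3.4))
#' est <- estimate_psf(bead)
#' est$sigma
#' @export
estimate_psf <- function(grid, average_halfwidth = 0L, min_margin_vox = 4L) {
  stopifnot(inherits(grid, "voxel_grid"))
  pos <- locate_bead(grid)                  # (iz, iy, ix), 0-based
  d <- dim(grid$data)
  if (any(pos < min_margin_vox) || any(pos > d - 1L - min_margin_vox))
    stop("bead lies at a stack face: line profiles would be truncated")
  h <- as.integer(average_halfwidth)
  iz <- pos[1] + 1L; iy <- pos[2] + 1L; ix <- pos[3] + 1L
  win <- function(i, n) max(1L, i - h):min(n, i + h)
  line_x <- apply(grid$data[win(iz, d[1]), win(iy, d[2]), , drop = FALSE],
                  3, mean)
  line_y <- apply(grid$data[win(iz, d[1]), , win(ix, d[3]), drop = FALSE],
                  2, mean)
  line_z <- apply(grid$data[, win(iy, d[2]), win(ix, d[3]), drop = FALSE],
                  1, mean)
  sp <- grid$spacing                        # (dz, dy, dx)
  fits <- list(x = fit_gaussian_profile(line_x, sp[3]),
               y = fit_gaussian_profile(line_y, sp[2]),
               z = fit_gaussian_profile(line_z, sp[1]))
  sigma <- vapply(fits, `[[`, numeric(1), "sigma")
  structure(list(sigma = sigma,
                 center_um = c(x = fits$x$center, y = fits$y$center,
                               z = fits$z$center),
                 fits = fits,
                 residual_rms = vapply(fits, `[[`, numeric(1), "residual_rms")),
            class = "psf_estimate")
}

#' @export
print.psf_estimate <- function(x, ...) {
  cat(sprintf("<psf_estimate> sigma (x, y, z) = (%.3g, %.3g, %.3g) um  [Gaussian SD, not FWHM]\n",
              x$sigma["x"], x$sigma["y"], x$sigma["z"]))
  cat(sprintf("  axial/lateral ratio %.2f; residual rms (x,y,z) = (%.3g, %.3g, %.3g)\n",
              x$sigma["z"] / x$sigma["x"], x$residual_rms["x"],
              x$residual_rms["y"], x$residual_rms["z"]))
  invisible(x)
}

#' @export
plot.psf_estimate <- function(x, axis = "z", ...) {
  plot(x$fits[[axis]], main = paste0("PSF line scan along ", axis), ...)
}
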