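#' 3D intensity stack with physical voxel spacing
#'
#' The unit of fluorescence imaging: a non-negative intensity array indexed
#' `[z, y, x]` (0-based voxel centers in physical coordinates: voxel
#' `(iz, iy, ix)` sits at `(ix*dx, iy*dy, iz*dz)` micrometres) together
#' with the voxel spacing `(dz, dy, dx)` in micrometres. `x` is the
#' capillary / anterior-posterior axis, `z` the detection (scan) axis.
#'
#' A 2D image (e.g. a maximum-intensity projection) is represented as a
#' grid with a single z-slice.
#'
#' @param data numeric 3D array with dim `(nz, ny, nx)`; a matrix is
#'   promoted to a single-slice grid.
#' @param spacing numeric length-3, `(dz, dy, dx)` in micrometres.
#' @return an object of class `voxel_grid` with elements `data` and
#'   `spacing`.
#' @examples
#' g <- voxel_grid(array(0, c(4, 8, 8)), spacing = c(2.5, 0.325, 0.325))
#' dim(g$data)
#' @export
voxel_grid <- function(data, spacing) {
  if (is.matrix(data)) data <- array(data, dim = c(1L, dim(data)))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array (or a matrix) with dim (nz, ny, nx)")
  if (!is.numeric(spacing) || length(spacing) != 3L || any(!is.finite(spacing)) ||
      any(spacing <= 0))
    stop("'spacing' must be three positive numbers (dz, dy, dx) in um")
  if (any(!is.finite(data))) stop("'data' must contain finite intensities")
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  ext <- rev((d - 1) * x$spacing)  # (x, y, z) extent in um
  cat(sprintf("<voxel_grid> %d x %d x %d voxels (z,y,x), spacing (%g, %g, %g) um\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  physical extent (x,y,z): %.1f x %.1f x %.1f um; intensity range [%g, %g]\n",
              ext[1], ext[2], ext[3], min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

#' Voxel volume in cubic micrometres
#' @param grid a [voxel_grid()].
#' @return scalar, `dz*dy*dx` in um^3.
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' Maximum intensity projection along the detection axis
#'
#' Collapses a 3D stack to the 2D image a simple widefield fluorescence
#' microscope would record: per `(y, x)` the maximum intensity over z.
#'
#' @param grid a [voxel_grid()].
#' @return a single-slice `voxel_grid`; the z spacing is set to 1 so that
#'   "volume" of a 2D object equals its area in um^2.
#' @export
max_projection <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$data)
  slices <- lapply(seq_len(d[1]), function(i) grid$data[i, , , drop = TRUE])
  mip <- Reduce(pmax, slices)
  voxel_grid(matrix(mip, d[2], d[3]), spacing = c(1, grid$spacing[2], grid$spacing[3]))
}
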