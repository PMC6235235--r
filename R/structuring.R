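# Structuring elements and neighbourhood offset tables, as (dz, dy, dx)
# integer matrices consumed by the C++ kernels. Masks and label arrays
# are plain logical / integer arrays with dim (nz, ny, nx).

#' Structuring-element offsets
#'
#' `"cross"` is the 6-connected cross of the given radius (offsets along
#' each axis only, the 3D analogue of a plus sign); `"cube"` the full
#' `(2r+1)^3` box. In a single-slice (2D) grid the z arms fall outside
#' the image, so the cross reduces to the 2D 4-cross and the cube to the
#' 8-neighbour square.
#'
#' @param radius non-negative integer, in voxels.
#' @param shape `"cross"` or `"cube"`.
#' @return integer matrix with columns (dz, dy, dx), including the origin.
#' @export
struct_element <- function(radius = 1L, shape = c("cross", "cube")) {
  shape <- match.arg(shape)
  radius <- as.integer(radius)
  if (radius < 0) stop("'radius' must be >= 0")
  if (radius == 0L) return(matrix(0L, 1L, 3L))
  if (shape == "cross") {
    r <- seq_len(radius)
    off <- rbind(c(0L, 0L, 0L),
                 cbind(c(r, -r), 0L, 0L),
                 cbind(0L, c(r, -r), 0L),
                 cbind(0L, 0L, c(r, -r)))
  } else {
    g <- expand.grid(dz = -radius:radius, dy = -radius:radius, dx = -radius:radius)
    off <- as.matrix(g)
  }
  storage.mode(off) <- "integer"
  dimnames(off) <- NULL
  off
}

#' Neighbourhood offsets for a voxel connectivity
#'
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (faces + edges
#'   + corners). In a single-slice grid these reduce to the 2D 4- and
#'   8-neighbourhoods.
#' @return integer matrix with columns (dz, dy, dx), origin excluded.
#' @export
connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6, 18, 26))
    stop("'connectivity' must be one of 6, 18, 26")
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  l1 <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6"  = l1 == 1,
                 "18" = l1 >= 1 & l1 <= 2,
                 "26" = l1 >= 1)
  off <- g[keep, , drop = FALSE]
  storage.mode(off) <- "integer"
  dimnames(off) <- NULL
  off
}

# Drop offset rows that step along singleton axes, so a single-slice
# (2D) grid gets true 2D morphology / connectivity: without this, the
# z arms of a 3D element would make erosion empty every 2D mask
# (out-of-bounds voxels are background).
restrict_offsets <- function(off, d) {
  keep <- rep(TRUE, nrow(off))
  for (a in 1:3) if (d[a] == 1L) keep <- keep & off[, a] == 0L
  off[keep, , drop = FALSE]
}

# Gaussian smoothing of a stack, separable, sigma per axis in voxels.
smooth_gaussian_vox <- function(arr, sigma_vox) {
  d <- dim(arr)
  out <- as.numeric(arr)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    h <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-h:h) / s)^2)
    k <- k / sum(k)
    out <- cpp_conv_axis(out, d, k, axis)
  }
  array(out, d)
}
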