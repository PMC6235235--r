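# Unit tests for each segmentation stage against hand-computed values
# and the brute-force oracles.

test_that("coarse threshold is strict and handles boundary cases", {
  g0 <- voxel_grid(array(0, c(3, 3, 3)), c(1, 1, 1))
  expect_false(any(coarse_threshold(g0, 5)))

  a <- array(0, c(3, 3, 3)); a[2, 2, 2] <- 10
  g <- voxel_grid(a, c(1, 1, 1))
  m <- coarse_threshold(g, 5)
  expect_identical(which(m), which(a == 10))
  expect_identical(as.vector(m), as.vector(oracle_threshold(a, 5)))
  expect_equal(attr(m, "threshold"), 5)

  # voxels exactly at the threshold stay background
  gu <- voxel_grid(array(7, c(3, 3, 3)), c(1, 1, 1))
  expect_false(any(coarse_threshold(gu, 7)))

  expect_error(coarse_threshold(g, list(method = "percentile", p = 0)),
               "percentile")
  expect_error(coarse_threshold(g, list(method = "percentile", p = 100)),
               "percentile")
})

test_that("morphological cleaning matches set-theoretic morphology", {
  e <- array(FALSE, c(5, 5, 5))
  expect_identical(morphological_clean(e, 1L), e)

  # a single isolated voxel: closing preserves it, erosion removes it
  one <- e; one[3, 3, 3] <- TRUE
  expect_false(any(morphological_clean(one, 1L)))

  # a solid 5x5x5 cube with the radius-1 cross leaves the 3x3x3 core
  cube <- array(TRUE, c(5, 5, 5))
  out <- morphological_clean(cube, 1L)
  expect_equal(sum(out), 27)
  expect_true(all(out[2:4, 2:4, 2:4]))
  expect_identical(out, oracle_clean(cube))

  # radius 0 is the identity
  expect_identical(morphological_clean(one, 0L), one)
})

test_that("component labeling respects connectivity and raster order", {
  e <- array(FALSE, c(4, 4, 4))
  expect_equal(attr(label_components(e), "n_labels"), 0)

  # two voxels sharing only a corner: separate under 6, joined under 26
  diag2 <- e; diag2[1, 1, 1] <- TRUE; diag2[2, 2, 2] <- TRUE
  expect_equal(attr(label_components(diag2, 6), "n_labels"), 2)
  expect_equal(attr(label_components(diag2, 26), "n_labels"), 1)

  full <- array(TRUE, c(4, 4, 4))
  expect_equal(attr(label_components(full, 6), "n_labels"), 1)

  # labels follow the raster order of each component's first voxel
  two <- e; two[4, 4, 4] <- TRUE; two[1, 1, 1] <- TRUE
  lab <- label_components(two, 6)
  expect_equal(lab[1, 1, 1], 1L)
  expect_equal(lab[4, 4, 4], 2L)
})

test_that("Otsu threshold maximizes between-class variance", {
  v <- c(1, 1, 2, 8, 9)
  expect_equal(otsu_threshold(v), 2)       # retains {8, 9}
  expect_equal(otsu_threshold(v), oracle_otsu(v))
  # the winning split's variance: 0.6*0.4*(8.5 - 4/3)^2
  expect_equal(0.6 * 0.4 * (mean(c(8, 9)) - mean(c(1, 1, 2)))^2,
               12.3266, tolerance = 1e-4)
  expect_error(otsu_threshold(c(5, 5, 5)), "distinct")

  for (seed in 1:20) {
    set.seed(seed)
    w <- round(c(rnorm(30, 10, 2), rnorm(10, 40, 3)))
    expect_equal(otsu_threshold(w), oracle_otsu(w))
  }
})

test_that("per-object Otsu refinement shrinks objects and respects rounds", {
  a <- array(0, c(1, 1, 5))
  a[1, 1, ] <- c(1, 1, 2, 8, 9)
  g <- voxel_grid(a, c(1, 1, 1))
  lab <- label_components(a > 0, 26)
  ref <- otsu_refine(g, lab, rounds = 1L)
  expect_identical(which(ref > 0), which(a >= 8))

  # rounds = 0 is the identity
  expect_identical(as.vector(otsu_refine(g, lab, rounds = 0L)), as.vector(lab))

  # uniform-intensity object passes through unchanged (degenerate)
  u <- array(0, c(3, 3, 3)); u[2, 2, 1:3] <- 5
  gu <- voxel_grid(u, c(1, 1, 1))
  labu <- label_components(u > 0, 26)
  expect_identical(as.vector(otsu_refine(gu, labu, rounds = 2L)), as.vector(labu))

  # monotone shrinkage: refined voxel sets are subsets of their parents
  set.seed(11)
  arr <- array(rpois(16^3, 10), c(16, 16, 16))
  arr[5:8, 5:8, 5:8] <- arr[5:8, 5:8, 5:8] + 60
  gg <- voxel_grid(arr, c(1, 1, 1))
  l0 <- label_components(arr > 25, 26)
  l1 <- otsu_refine(gg, l0, rounds = 1L)
  l2 <- otsu_refine(gg, l0, rounds = 2L)
  expect_true(all(which(l1 > 0) %in% which(l0 > 0)))
  expect_true(all(which(l2 > 0) %in% which(l1 > 0)))
})

test_that("volume filter uses physical units", {
  sp <- c(2.5, 0.325, 0.325)                 # voxel = 0.2640625 um^3
  a <- array(0L, c(4, 8, 8))
  a[2, 1:2, 1:5] <- 1L                       # 10 voxels = 2.64 um^3
  a[3, 5:7, 5:8] <- 1L                       # 12 voxels = 3.17 um^3
  lab <- label_components(a > 0, 26)
  expect_equal(attr(lab, "n_labels"), 2)
  out <- filter_small_objects(lab, sp, min_volume = 3)
  expect_equal(attr(out, "n_labels"), 1)
  expect_true(all(out[a == 1L][lab[a == 1L] == 2] == 1L))  # survivor relabeled 1

  # min_volume 0 is the identity; all-below gives an empty result
  expect_equal(attr(filter_small_objects(lab, sp, 0), "n_labels"), 2)
  none <- filter_small_objects(lab, sp, min_volume = 100)
  expect_equal(attr(none, "n_labels"), 0)
  expect_true(all(none == 0L))
})

test_that("object measurement: centroids, intensities, bounding boxes", {
  sp <- c(1, 1, 2)                           # dx = 2 um
  a <- array(0, c(3, 3, 16))
  a[2, 2, 11] <- 5; a[2, 2, 13] <- 5         # x indices 10 and 12 (0-based)
  g <- voxel_grid(a, sp)
  lab <- array(0L, dim(a))
  lab[a > 0] <- 1L                           # one object, both voxels
  obj <- measure_objects(g, lab)
  expect_equal(nrow(obj), 1)
  expect_equal(obj$x_um, 11 * 2)             # equal weights: midpoint
  expect_equal(obj$total_intensity, 10)
  expect_equal(obj$voxels, 2L)
  expect_equal(obj$bbox_x0, 10L)
  expect_equal(obj$bbox_x1, 12L)

  # object intensities never exceed the grid total
  set.seed(3)
  arr <- array(rpois(10^3, 8), c(10, 10, 10))
  gg <- voxel_grid(arr, c(1, 1, 1))
  ll <- label_components(arr > 10, 26)
  oo <- measure_objects(gg, ll)
  expect_lte(sum(oo$total_intensity), sum(arr))
  expect_equal(nrow(measure_objects(gg, array(0L, dim(arr)))), 0)
})

test_that("full pipeline recovers planted blobs and rejects blanks", {
  blank <- make_neutrophil_stack(stack_recipe(shape = c(16, 32, 32),
                                              voxel_spacing = c(2.5, 1, 1),
                                              noise_model = "poisson", seed = 2))
  expect_equal(nrow(segment_stack(blank$grid)$objects), 0)

  spacing <- c(2.5, 0.65, 0.65)
  shape <- c(48L, 96L, 96L)
  centers <- place_separated_centers(8, rev((shape - 1) * spacing),
                                     margin_xyz = c(10, 10, 12),
                                     min_separation = 22, seed = 5)
  blobs <- lapply(seq_len(8), function(i)
    blob_spec(centers[i, ], c(3, 3, 3), 800))
  st <- make_neutrophil_stack(stack_recipe(shape = shape, voxel_spacing = spacing,
                                           blobs = blobs, seed = 5))
  seg <- segment_stack(st$grid)
  expect_equal(nrow(seg$objects), 8)
  # every recovered centroid lies within 2 um of a planted center
  d <- vapply(seq_len(8), function(i) {
    min(sqrt(colSums((t(centers) - unlist(seg$objects[i, c("x_um", "y_um", "z_um")]))^2)))
  }, numeric(1))
  expect_true(all(d < 2))
  expect_true(all(seg$objects$volume_um3 >= 3))
})

test_that("projection counting merges occluded cells", {
  spacing <- c(2.5, 0.65, 0.65)
  mk <- function(blobs) make_neutrophil_stack(
    stack_recipe(shape = c(48, 64, 64), voxel_spacing = spacing,
                 blobs = blobs, noise_model = "none"))$grid
  # same (x, y), different z: two in 3D, one in projection
  occl <- mk(list(blob_spec(c(20, 20, 30), c(3, 3, 3), 900),
                  blob_spec(c(20, 20, 85), c(3, 3, 3), 900)))
  expect_equal(nrow(segment_stack(occl)$objects), 2)
  expect_equal(as.integer(count_projection(occl)), 1)

  # disjoint in projection: counts agree
  disj <- mk(list(blob_spec(c(14, 14, 40), c(3, 3, 3), 900),
                  blob_spec(c(27, 27, 75), c(3, 3, 3), 900)))
  expect_equal(nrow(segment_stack(disj)$objects), 2)
  expect_equal(as.integer(count_projection(disj)), 2)

  blank <- voxel_grid(array(100, c(16, 32, 32)), spacing)
  expect_equal(as.integer(count_projection(blank)), 0)
})

test_that("morphology and labeling agree with scipy.ndimage", {
  py <- Sys.which("python")
  expect_true(nzchar(py))
  set.seed(17)
  d <- c(9, 11, 10)
  mask <- array(runif(prod(d)) < 0.35, d)
  fm <- tempfile(fileext = ".txt")
  writeLines(as.character(as.integer(mask)), fm)
  out <- tempfile(fileext = ".txt")
  code <- sprintf(paste0(
    "import numpy as np\n",
    "from scipy import ndimage\n",
    "m = np.loadtxt(%s).astype(bool).reshape((%d, %d, %d), order='F')\n",
    "se = ndimage.generate_binary_structure(3, 1)\n",
    "p = np.pad(m, 1)\n",                     # embed in background
    "closed = ndimage.binary_erosion(ndimage.binary_dilation(p, se), se)\n",
    "cleaned = ndimage.binary_erosion(closed, se)[1:-1, 1:-1, 1:-1]\n",
    "lab, n = ndimage.label(m, structure=np.ones((3, 3, 3)))\n",
    "np.savetxt(%s, np.concatenate([cleaned.flatten(order='F').astype(int),\n",
    "                               [n]]), fmt='%%d')\n"),
    deparse(fm), d[1], d[2], d[3], deparse(out))
  system2(py, c("-c", shQuote(code)))
  ref <- as.integer(readLines(out))
  expect_identical(as.integer(morphological_clean(mask, 1L)),
                   head(ref, -1))
  expect_equal(attr(label_components(mask, 26), "n_labels"), tail(ref, 1))
})
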