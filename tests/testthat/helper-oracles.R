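# Independent brute-force reference implementations used to verify the
# segmentation stages voxel-for-voxel on small stacks. Deliberately
# naive: direct set definitions and exhaustive searches, sharing no code
# with the package internals.

# thresholding: direct per-voxel comparison in a loop
oracle_threshold <- function(arr, thr) {
  out <- array(FALSE, dim(arr))
  for (i in seq_along(arr)) out[i] <- arr[i] > thr
  out
}

oracle_offsets <- function(kind, radius = 1L, connectivity = NULL, d) {
  if (kind == "cross") {
    off <- list(c(0, 0, 0))
    for (a in 1:3) for (r in seq_len(radius)) {
      v <- c(0, 0, 0); v[a] <- r; off <- c(off, list(v))
      v[a] <- -r; off <- c(off, list(v))
    }
  } else if (kind == "conn") {
    off <- list()
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      l1 <- abs(dz) + abs(dy) + abs(dx)
      ok <- switch(as.character(connectivity),
                   "6" = l1 == 1, "18" = l1 >= 1 && l1 <= 2, "26" = l1 >= 1)
      if (ok) off <- c(off, list(c(dz, dy, dx)))
    }
  }
  # keep only offsets usable in this grid (singleton axes have no arms)
  Filter(function(v) all(v[d == 1L] == 0), off)
}

# set-definition dilation/erosion; out of bounds = background
oracle_dilate <- function(mask, off) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    hit <- FALSE
    for (v in off) {
      p <- c(z, y, x) + v
      if (all(p >= 1) && all(p <= d) && mask[p[1], p[2], p[3]]) { hit <- TRUE; break }
    }
    out[z, y, x] <- hit
  }
  out
}

oracle_erode <- function(mask, off) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    all_in <- TRUE
    for (v in off) {
      p <- c(z, y, x) + v
      if (any(p < 1) || any(p > d) || !mask[p[1], p[2], p[3]]) { all_in <- FALSE; break }
    }
    out[z, y, x] <- all_in
  }
  out
}

# embed in an infinite background: pad by the radius, operate, crop
oracle_clean <- function(mask, radius = 1L) {
  d <- dim(mask)
  pad <- ifelse(d == 1L, 0L, radius)
  big <- array(FALSE, d + 2L * pad)
  big[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), pad[3] + seq_len(d[3])] <- mask
  off <- oracle_offsets("cross", radius = radius, d = d)
  out <- oracle_erode(oracle_erode(oracle_dilate(big, off), off), off)
  out[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), pad[3] + seq_len(d[3]),
      drop = FALSE]
}

# flood-fill labeling, seeds in raster (linear index) order
oracle_label <- function(mask, connectivity) {
  d <- dim(mask)
  off <- oracle_offsets("conn", connectivity = connectivity, d = d)
  lab <- array(0L, d)
  nxt <- 0L
  for (i in seq_along(mask)) {
    if (!mask[i] || lab[i] != 0L) next
    nxt <- nxt + 1L
    queue <- i
    lab[i] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      iz <- (cur - 1) %% d[1] + 1
      iy <- ((cur - 1) %/% d[1]) %% d[2] + 1
      ix <- (cur - 1) %/% (d[1] * d[2]) + 1
      for (v in off) {
        p <- c(iz, iy, ix) + v
        if (all(p >= 1) && all(p <= d)) {
          j <- p[1] + d[1] * (p[2] - 1 + d[2] * (p[3] - 1))
          if (mask[j] && lab[j] == 0L) { lab[j] <- nxt; queue <- c(queue, j) }
        }
      }
    }
  }
  lab
}

# exhaustive Otsu: for every candidate threshold compute the two class
# means directly and maximize the between-class variance
oracle_otsu <- function(v) {
  cand <- sort(unique(v))
  cand <- cand[-length(cand)]
  best <- -Inf; t_star <- NA
  for (t in cand) {
    lo <- v[v <= t]; hi <- v[v > t]
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best + 1e-12) { best <- bcv; t_star <- t }
  }
  t_star
}

# exhaustive cross-correlation scorer for 1D profiles: naive loop over
# shifts, Pearson correlation accumulated sample by sample per overlap
oracle_crosscorr <- function(p, q, max_k, min_overlap) {
  best_k <- NA; best <- -Inf
  for (k in -max_k:max_k) {
    xs <- c(); ys <- c()
    for (i in seq_along(p)) {
      j <- i - k
      if (j >= 1 && j <= length(q)) { xs <- c(xs, p[i]); ys <- c(ys, q[j]) }
    }
    if (length(xs) < min_overlap) next
    den <- sqrt(sum((xs - mean(xs))^2) * sum((ys - mean(ys))^2))
    if (den == 0) next
    score <- sum((xs - mean(xs)) * (ys - mean(ys))) / den
    if (score > best + 1e-12 || (abs(score - best) <= 1e-12 && abs(k) < abs(best_k))) {
      best <- score; best_k <- k
    }
  }
  best_k
}

# small random test stack
random_stack <- function(seed, max_dim = 16L) {
  set.seed(seed)
  d <- sample(6:max_dim, 3, replace = TRUE)
  arr <- array(rpois(prod(d), 20) + round(runif(prod(d)) * 5), d)
  # sprinkle a few bright clusters so thresholds bite
  for (k in 1:3) {
    p <- sapply(d, function(n) sample(2:(n - 1), 1))
    arr[p[1], p[2], p[3]] <- arr[p[1], p[2], p[3]] + sample(50:150, 1)
  }
  voxel_grid(arr, spacing = c(2.5, 0.325, 0.325))
}
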