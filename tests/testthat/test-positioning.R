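# Profile extraction, tiling, template building and offset matching.

test_that("profile extraction averages frames along y", {
  const <- matrix(7, 10, 20)
  expect_true(all(profile_from_image(const, 3)$values == 7))

  dark <- matrix(100, 10, 20); dark[, 13] <- 10
  expect_equal(which.min(profile_from_image(dark, 3)$values), 13)

  set.seed(2)
  rnd <- matrix(runif(200), 10, 20)
  brute <- vapply(1:20, function(j) mean(rnd[, j]), numeric(1))
  expect_equal(profile_from_image(rnd, 3)$values, brute)
})

test_that("composite tiling places frames and averages overlaps", {
  f <- matrix(runif(40), 4, 10)
  expect_equal(tile_composite(list(f), 10, 1), f)

  # two abutting frames of width w at step w
  f2 <- matrix(2, 4, 10)
  comp <- tile_composite(list(f, f2), step_um = 10, pixel_um = 1)
  expect_equal(dim(comp), c(4, 20))
  expect_equal(comp[, 1:10], f)
  expect_true(all(comp[, 11:20] == 2))

  # 50% overlap of constant frames 1, 2, 3: bands average to 1.5 and 2.5
  cs <- lapply(1:3, function(v) matrix(v, 4, 10))
  comp3 <- tile_composite(cs, step_um = 5, pixel_um = 1)
  expect_equal(dim(comp3)[2], 20)
  expect_true(all(comp3[, 1:5] == 1))
  expect_true(all(comp3[, 6:10] == 1.5))
  expect_true(all(comp3[, 11:15] == 2.5))
  expect_true(all(comp3[, 16:20] == 3))

  expect_error(tile_composite(list(f, matrix(1, 5, 10)), 10, 1), "height")
})

test_that("template building normalizes then averages", {
  p <- make_brightfield_profile(profile_recipe(noise_sigma = 0))
  t1 <- build_template(list(p, p, p))
  nv <- (p$values - mean(p$values)) / sd(p$values)
  expect_equal(t1$values, nv)
  expect_equal(build_template(list(p))$values, nv)

  p2 <- make_brightfield_profile(profile_recipe(noise_sigma = 4, seed = 2))
  n2 <- (p2$values - mean(p2$values)) / sd(p2$values)
  expect_equal(build_template(list(p, p2))$values, (nv + n2) / 2)

  p3 <- intensity_profile(p$values, step = p$step * 2)
  expect_error(build_template(list(p, p3)), "steps")
})

test_that("offset matching recovers planted shifts exactly when noise-free", {
  tpl <- make_brightfield_profile(profile_recipe(noise_sigma = 0))
  expect_equal(match_offset(tpl, tpl, "crosscorr", 800)$offset, 0)
  expect_equal(match_offset(tpl, tpl, "minimum", 800)$offset, 0)

  # +7 samples at 3 um step = +21 um, both methods
  r3 <- profile_recipe(length = 500, step = 3,
                       feature_positions = c(300, 900),
                       feature_depths = c(0.7, 0.4),
                       feature_widths = c(60, 90), noise_sigma = 0)
  t3 <- make_brightfield_profile(r3)
  r3s <- r3; r3s$offset <- 21
  p3 <- make_brightfield_profile(r3s)
  expect_equal(match_offset(p3, t3, "crosscorr", 300)$offset, 21)
  expect_equal(match_offset(p3, t3, "minimum", 300)$offset, 21)

  # crosscorr equals the exhaustive brute-force scorer
  for (off_um in c(-60, 0, 33)) {
    rs <- r3; rs$offset <- off_um
    p <- make_brightfield_profile(rs)
    k <- oracle_crosscorr(p$values, t3$values, max_k = 40,
                          min_overlap = ceiling(0.25 * 500))
    expect_equal(match_offset(p, t3, "crosscorr", 120)$offset, k * 3)
  }

  expect_error(match_offset(p3, t3, "crosscorr", max_shift = 1e6), "extent")
})

test_that("offset matching is shift-equivariant on integer-sample shifts", {
  r <- profile_recipe(length = 400, step = 5, feature_positions = c(700, 1300),
                      feature_depths = c(0.6, 0.3), feature_widths = c(80, 100),
                      noise_sigma = 0)
  tpl <- make_brightfield_profile(r)
  base <- match_offset(make_brightfield_profile(r), tpl, "crosscorr", 600)$offset
  for (d in c(-200, -45, 55, 300)) {
    rs <- r; rs$offset <- d
    sh <- match_offset(make_brightfield_profile(rs), tpl, "crosscorr", 600)$offset
    expect_equal(sh, base + d)
  }
})

test_that("both methods agree within one sample and tolerate 5% noise", {
  r <- profile_recipe(noise_sigma = 0)
  tpl <- make_brightfield_profile(r)
  amp <- max(tpl$values) - min(tpl$values)
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    d <- sample(seq(-300, 300, by = 10), 1)
    rs <- r; rs$offset <- d; rs$noise_sigma <- 0.05 * amp; rs$seed <- seed
    p <- make_brightfield_profile(rs)
    got <- match_offset(p, tpl, "crosscorr", 600)$offset
    if (abs(got - d) <= p$step) hits <- hits + 1L
  }
  expect_gte(hits, 95)

  # noise-free: crosscorr and minimum indistinguishable (<= 1 sample)
  for (d in c(-120, 0, 90)) {
    rs <- r; rs$offset <- d
    p <- make_brightfield_profile(rs)
    cc <- match_offset(p, tpl, "crosscorr", 600)$offset
    mn <- match_offset(p, tpl, "minimum", 600)$offset
    expect_lte(abs(cc - mn), p$step)
  }
})

test_that("template libraries pick the best-matching entry", {
  fish5 <- make_brightfield_profile(profile_recipe(noise_sigma = 0))
  fish6 <- make_brightfield_profile(profile_recipe(
    feature_positions = c(800, 2400, 3300), feature_depths = c(0.5, 0.6, 0.2),
    feature_widths = c(180, 200, 140), noise_sigma = 0))
  lib <- template_library(list(dpf5 = fish5, dpf6 = fish6))
  shifted <- make_brightfield_profile(profile_recipe(offset = 150,
                                                     noise_sigma = 0))
  res <- match_offset(shifted, lib, "crosscorr", 600)
  expect_equal(res$best_template, "dpf5")
  expect_equal(res$offset, 150)
})

test_that("closed-loop fine positioning corrects a large initial offset", {
  tpl <- make_brightfield_profile(profile_recipe(noise_sigma = 0))
  # zero noise: the first correction nulls the displacement exactly
  traj <- simulate_fine_positioning(tpl, true_offset = 900)
  expect_equal(traj$residual[1], 0)
  expect_true(attr(traj, "converged"))

  expect_error(simulate_fine_positioning(tpl, 900, max_iter = 0), "max_iter")

  # determinism under a fixed seed
  t1 <- simulate_fine_positioning(tpl, 500, stage_noise_sd = 10,
                                  profile_noise_sd = 5, seed = 42)
  t2 <- simulate_fine_positioning(tpl, 500, stage_noise_sd = 10,
                                  profile_noise_sd = 5, seed = 42)
  expect_identical(t1$residual, t2$residual)
})
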