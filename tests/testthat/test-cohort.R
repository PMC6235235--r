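# Cohort statistics: summaries, regression, histograms, group
# comparison, projection ratio, and the instrument arithmetic.

test_that("count summaries use the sample SD and flag singletons", {
  s <- summarize_counts(fish_records(c(80, 100, 120)))
  expect_equal(s$mean, 100)
  expect_equal(s$sd, 20)
  expect_equal(s$sd_over_mean, 0.20)

  expect_equal(summarize_counts(fish_records(rep(55, 6)))$sd, 0)

  s1 <- summarize_counts(fish_records(90))
  expect_false(s1$sd_defined)
})

test_that("intensity-count regression matches the closed-form mixture model", {
  rec <- fish_records(c(1, 2, 3, 4), intensity = c(2, 4, 6, 8))
  r <- suppressWarnings(regress_intensity_on_count(rec))
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 0)

  expect_error(regress_intensity_on_count(
    fish_records(c(5, 5, 5), intensity = c(1, 2, 3))), "variance")
  expect_error(regress_intensity_on_count(fish_records(c(1, 2))), "3 fish")

  # per-cell cv 0.8, n = 500: R^2 within 0.05 of the analytic value
  rec2 <- make_cohort_tables(500, cell_cv = 0.8, seed = 12)
  r2 <- regress_intensity_on_count(rec2)
  expected <- expected_r_squared(90, 27, 0.8)
  expect_equal(r2$r_squared, expected, tolerance = 0.05 / expected)
  expect_true(abs(r2$r_squared - expected) < 0.05)
})

test_that("AP histograms pool fish with half-open bins and conserve counts", {
  rec <- fish_records(3, ap_positions = list(c(10, 10, 250)))
  h <- ap_histogram(rec, bin_width = 100)
  expect_equal(h$counts, c(2L, 0L, 1L))
  expect_equal(h$bin_edges, c(0, 100, 200, 300))

  # conservation across several fish
  rec2 <- fish_records(c(2, 3), ap_positions = list(c(5, 660), c(100, 100, 333)))
  h2 <- ap_histogram(rec2, bin_width = 50)
  expect_equal(sum(h2$counts), 5)

  # a position on a bin edge belongs to the right-hand bin
  h3 <- ap_histogram(fish_records(1, ap_positions = list(100)), bin_width = 100)
  expect_equal(h3$counts, c(0L, 1L))

  h0 <- ap_histogram(fish_records(0, ap_positions = list(numeric(0))), 50)
  expect_true(all(h0$counts == 0))
})

test_that("group comparison: fold change, propagated error, bootstrap", {
  a <- fish_records(c(80, 90, 100))
  expect_equal(compare_groups(a, a, n_boot = 100)$fold, 1.0)

  # constructed groups with the 6-dpf control/LPS means: fold 1.2008
  ctrl <- fish_records(c(rep(95, 19), 96.05, 96.05))   # mean 95.1, N = 21
  lps <- fish_records(c(rep(114, 17), 115.9, 115.9))   # mean 114.2, N = 19
  cmp <- compare_groups(ctrl, lps, n_boot = 1000, seed = 3)
  expect_equal(cmp$fold, 114.2 / 95.1, tolerance = 1e-12)
  expect_equal(cmp$fold, 1.2008, tolerance = 1e-4)

  # propagated SE agrees with the hand formula
  x <- fish_records(c(70, 85, 92, 110)); y <- fish_records(c(100, 120, 140))
  cm <- compare_groups(x, y, n_boot = 500, seed = 5)
  fold <- mean(y$count) / mean(x$count)
  se <- fold * sqrt((sd(y$count) / sqrt(3) / mean(y$count))^2 +
                    (sd(x$count) / sqrt(4) / mean(x$count))^2)
  expect_equal(cm$fold_se, se)

  # bootstrap is seed-deterministic and brackets the estimate
  cm2 <- compare_groups(x, y, n_boot = 500, seed = 5)
  expect_identical(cm$fold_ci, cm2$fold_ci)
  expect_lt(cm$fold_ci[1], fold)
  expect_gt(cm$fold_ci[2], fold)

  expect_error(compare_groups(fish_records(c(0, 0)), y), "zero")
  expect_error(compare_groups(fish_records(5), y), "2 fish")
})

test_that("projection ratios average per-fish 2D/3D fractions", {
  r <- projection_ratio(c(3, 1, 9), c(4, 2, 10))
  expect_equal(r$mean_ratio, (0.75 + 0.5 + 0.9) / 3)
  expect_equal(r$n, 3)

  req <- projection_ratio(c(5, 7), c(5, 7))
  expect_equal(req$mean_ratio, 1)
  expect_equal(req$sem, 0)

  rz <- projection_ratio(c(3, 0), c(4, 0))
  expect_equal(rz$n, 1)
  expect_equal(rz$n_excluded, 1)
  expect_error(projection_ratio(numeric(0), numeric(0)), "no pairs|paired")
})

test_that("statistics are invariant under positive rescaling", {
  set.seed(31)
  counts <- rpois(40, 90)
  inten <- counts * 800 + rnorm(40, 0, 5000)
  rec1 <- fish_records(counts, intensity = pmax(inten, 0))
  rec3 <- fish_records(3 * counts, intensity = pmax(inten, 0) * 2)
  expect_equal(summarize_counts(rec1)$sd_over_mean,
               summarize_counts(rec3)$sd_over_mean)
  expect_equal(regress_intensity_on_count(rec1)$r_squared,
               regress_intensity_on_count(rec3)$r_squared)
  expect_equal(compare_groups(rec1, rec1, n_boot = 10)$fold,
               compare_groups(rec3, rec3, n_boot = 10)$fold)
  expect_equal(projection_ratio(2 * counts, 2 * counts * 2)$mean_ratio,
               projection_ratio(counts, counts * 2)$mean_ratio)
})

test_that("instrument arithmetic reproduces the printed scan and flow figures", {
  expect_equal(scan_volume_mm3(), 666 * 431 * 1060 / 1e9)
  expect_equal(scan_volume_mm3(), 0.3, tolerance = 0.02)
  expect_equal(flow_speed_cm_s(), 4, tolerance = 0.1)     # "4 cm/sec"
  expect_equal(flow_speed_cm_s(1, 0.7),
               (1000 / 60) / (pi * 0.35^2) / 10)
})
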