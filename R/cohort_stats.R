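# Cohort-level statistics over per-fish records.
#
# A fish record carries a neutrophil count, optionally the summed
# fluorescence intensity of its detected neutrophils, a group label
# (e.g. control / LPS, dpf) and optionally the anterior-posterior
# positions of its neutrophils. All SDs are sample SDs (n - 1).

#' Construct per-fish records
#'
#' @param count integer neutrophil counts, one per fish.
#' @param intensity optional summed fluorescence per fish.
#' @param group optional group label per fish.
#' @param ap_positions optional list (one element per fish) of
#'   anterior-posterior neutrophil positions in um.
#' @param fish_id optional ids.
#' @return data.frame of class `fish_records` (ap positions kept as a
#'   list column).
#' @export
fish_records <- function(count, intensity = NULL, group = NULL,
                         ap_positions = NULL, fish_id = NULL) {
  n <- length(count)
  if (n < 1L) stop("at least one fish record is required")
  if (any(count < 0)) stop("counts must be >= 0")
  if (!is.null(intensity) && (length(intensity) != n || any(intensity < 0)))
    stop("'intensity' must be non-negative, one value per fish")
  out <- data.frame(fish_id = fish_id %||% seq_len(n),
                    count = as.numeric(count))
  out$intensity <- if (is.null(intensity)) NA_real_ else as.numeric(intensity)
  out$group <- if (is.null(group)) NA_character_ else as.character(group)
  if (!is.null(ap_positions)) {
    if (length(ap_positions) != n)
      stop("'ap_positions' must have one element per fish")
    out$ap_positions <- I(ap_positions)
  }
  class(out) <- c("fish_records", "data.frame")
  out
}

#' Summarize neutrophil counts of a group
#'
#' @param records a [fish_records()] data.frame (or anything with a
#'   `count` column).
#' @return list of class `group_summary`: `n`, `mean`, `sd`,
#'   `sd_over_mean`, and `sd_defined` (`FALSE` for a single fish).
#' @examples
#' summarize_counts(fish_records(c(80, 100, 120)))
#' @export
summarize_counts <- function(records) {
  x <- records$count
  if (is.null(x) || length(x) < 1L) stop("records must contain counts")
  n <- length(x)
  m <- mean(x)
  s <- if (n > 1L) sd(x) else NA_real_
  structure(list(n = n, mean = m, sd = s,
                 sd_over_mean = if (n > 1L && m > 0) s / m else NA_real_,
                 sd_defined = n > 1L),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  if (x$sd_defined)
    cat(sprintf("%.1f +/- %.1f neutrophils (mean +/- SD, N = %d); SD/mean = %.2f\n",
                x$mean, x$sd, x$n, x$sd_over_mean))
  else
    cat(sprintf("%.1f neutrophils (N = 1; SD undefined)\n", x$mean))
  invisible(x)
}

#' Regress total fluorescence on neutrophil count
#'
#' Ordinary least squares (with intercept) of per-fish total intensity on
#' per-fish count; the coefficient of determination measures how well
#' bulk brightness predicts actual cell number.
#'
#' @param records a [fish_records()] with both `count` and `intensity`.
#' @return list of class `count_regression`: `slope`, `intercept`,
#'   `r_squared`, `n`, and the underlying `lm` fit.
#' @export
regress_intensity_on_count <- function(records) {
  ok <- complete.cases(records$count, records$intensity)
  d <- data.frame(count = records$count[ok], intensity = records$intensity[ok])
  if (nrow(d) < 3L) stop("need at least 3 fish with both count and intensity")
  if (var(d$count) == 0) stop("counts have zero variance: slope undefined")
  fit <- lm(intensity ~ count, data = d)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n = nrow(d), fit = fit),
            class = "count_regression")
}

#' @export
print.count_regression <- function(x, ...) {
  cat(sprintf("intensity ~ count: slope %.4g, intercept %.4g, R^2 = %.3f (N = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Expected R-squared of the count-mixture model
#'
#' Closed form for cohorts where per-fish intensity is the sum over cells
#' of i.i.d. per-cell intensities with coefficient of variation `cv`:
#' `R^2 = var(N) / (var(N) + mean(N) * cv^2)`.
#'
#' @param mean_count,sd_count moments of the count distribution.
#' @param cell_cv per-cell intensity coefficient of variation.
#' @return the population R-squared.
#' @export
expected_r_squared <- function(mean_count, sd_count, cell_cv) {
  v <- sd_count^2
  v / (v + mean_count * cell_cv^2)
}

#' Pooled histogram of neutrophil positions along the AP axis
#'
#' @param records a [fish_records()] with an `ap_positions` list column.
#' @param bin_width bin width in um (default 50 over the ~666 um field).
#' @param origin left edge of the first bin, um.
#' @return list of class `ap_histogram`: `bin_edges` (length nbins + 1),
#'   `counts` summed over fish; bins are half-open `[edge, edge + width)`.
#' @export
ap_histogram <- function(records, bin_width = 50, origin = 0) {
  if (is.null(records$ap_positions))
    stop("records carry no anterior-posterior positions")
  stopifnot_scalar_pos(bin_width, "bin_width")
  pos <- unlist(records$ap_positions, use.names = FALSE)
  if (length(pos) == 0L) {
    edges <- origin + bin_width * (0:1)
    return(structure(list(bin_edges = edges, counts = 0L),
                     class = "ap_histogram"))
  }
  if (any(pos < origin)) stop("positions below the histogram origin")
  nb <- max(1L, ceiling((max(pos) - origin) / bin_width + 1e-12))
  idx <- pmin(nb, floor((pos - origin) / bin_width) + 1L)  # [edge, edge+w)
  structure(list(bin_edges = origin + bin_width * (0:nb),
                 counts = tabulate(idx, nbins = nb)),
            class = "ap_histogram")
}

#' @export
plot.ap_histogram <- function(x, ...) {
  nb <- length(x$counts)
  mid <- (x$bin_edges[-1] + x$bin_edges[-(nb + 1)]) / 2
  plot(mid, x$counts, type = "h", lwd = 6, lend = 1,
       xlab = "anterior-posterior position (um)",
       ylab = "neutrophil count (all fish)", ...)
  invisible(x)
}

#' Compare neutrophil counts between two groups
#'
#' Reports both group summaries and the fold change of the means
#' (treated / control). The fold uncertainty is computed two ways:
#' first-order propagation of the two standard errors of the mean,
#' `fold * sqrt((sem_t/mean_t)^2 + (sem_c/mean_c)^2)`, and a seeded
#' nonparametric bootstrap interval.
#'
#' @param control,treated [fish_records()] for the two groups (n >= 2
#'   each).
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed for the bootstrap.
#' @return list of class `group_comparison`: `control`, `treated`
#'   (group_summary), `fold`, `fold_se` (propagated), `fold_ci`
#'   (2.5/97.5% bootstrap percentiles), `n_boot`.
#' @export
compare_groups <- function(control, treated, n_boot = 10000L, seed = 1L) {
  sc <- summarize_counts(control)
  st <- summarize_counts(treated)
  if (sc$n < 2L || st$n < 2L) stop("both groups need at least 2 fish")
  if (sc$mean == 0) stop("control mean is zero: fold change undefined")
  fold <- st$mean / sc$mean
  sem_c <- sc$sd / sqrt(sc$n)
  sem_t <- st$sd / sqrt(st$n)
  fold_se <- fold * sqrt((sem_t / st$mean)^2 + (sem_c / sc$mean)^2)
  xc <- control$count
  xt <- treated$count
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      mean(sample(xt, length(xt), replace = TRUE)) /
        mean(sample(xc, length(xc), replace = TRUE))
    }, numeric(1))
  })
  structure(list(control = sc, treated = st, fold = fold, fold_se = fold_se,
                 fold_ci = quantile(boots, c(0.025, 0.975), names = FALSE),
                 n_boot = n_boot),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("control: "); print(x$control)
  cat("treated: "); print(x$treated)
  cat(sprintf("fold change %.2f +/- %.2f (propagated); bootstrap 95%% CI [%.2f, %.2f]\n",
              x$fold, x$fold_se, x$fold_ci[1], x$fold_ci[2]))
  invisible(x)
}

#' Ratio of 2D-projection counts to 3D counts
#'
#' Per fish the ratio `count2d / count3d`; pairs with a zero 3D count
#' are excluded (and reported). The mean ratio below 1 quantifies the
#' undercount of widefield-style projection imaging caused by cells
#' occluding one another along z.
#'
#' @param count2d,count3d paired per-fish counts.
#' @return list of class `projection_ratio`: `mean_ratio`, `sem`, `n`,
#'   `ratios`, `n_excluded`.
#' @examples
#' projection_ratio(c(3, 1, 9), c(4, 2, 10))$mean_ratio
#' @export
projection_ratio <- function(count2d, count3d) {
  if (length(count2d) != length(count3d)) stop("counts must be paired")
  keep <- count3d > 0
  n_exc <- sum(!keep)
  r <- count2d[keep] / count3d[keep]
  if (length(r) < 1L) stop("no pairs with a positive 3D count")
  structure(list(mean_ratio = mean(r),
                 sem = if (length(r) > 1L) sd(r) / sqrt(length(r)) else NA_real_,
                 n = length(r), ratios = r, n_excluded = n_exc),
            class = "projection_ratio")
}

#' @export
print.projection_ratio <- function(x, ...) {
  cat(sprintf("2D/3D count ratio %.3f +/- %.3f (mean +/- SEM, N = %d%s)\n",
              x$mean_ratio, x$sem, x$n,
              if (x$n_excluded) paste0("; ", x$n_excluded, " zero-count pairs excluded")
              else ""))
  invisible(x)
}
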