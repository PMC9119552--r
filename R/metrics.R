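#' Completion rate among accepted applicants
#'
#' `100 * mean(outcome | accepted)`, the percentage printed in the corner
#' of each grid cell.
#'
#' @param mask an `"acceptance_mask"`.
#' @param outcomes a [sample_outcomes()] object (or bare 0/1 vector).
#' @return completion percentage in \[0, 100\].
#' @export
completion_rate <- function(mask, outcomes) {
  stopifnot(inherits(mask, "acceptance_mask"))
  y <- if (inherits(outcomes, "completion_outcomes")) outcomes$outcome else
    outcomes
  if (mask$n_accepted < 1L) stop("no accepted applicants", call. = FALSE)
  100 * mean(y[mask$accepted])
}

#' Acceptance and completion curves over test-percentile bins
#'
#' Bins the continuous test percentile (in (0, 100]) into integer bins
#' 1..100 by the ceiling, then computes per bin: the fraction of ALL
#' applicants in the bin who were accepted, and the mean completion
#' outcome among the ACCEPTED applicants in the bin. A bin enters the
#' curve statistics (is "occupied") only when it holds at least
#' `min_count` accepted applicants AND its acceptance rate is at least
#' `min_acceptance`; other bins have an `NA` completion rate (never
#' zero). The acceptance floor restricts the curve to the percentile
#' range where acceptance is non-negligible — the range a plotted
#' acceptance-probability curve visibly covers — and makes the occupied
#' set independent of the cohort size. Under highly selective policies
#' the excluded sparse low-percentile bins hold rare, heavily compensated
#' admits whose completion behaviour is not part of the plotted
#' relationship.
#'
#' @param test_percentiles numeric vector of test percentiles in (0, 100].
#' @param mask an `"acceptance_mask"`.
#' @param outcomes a [sample_outcomes()] object (or bare 0/1 vector).
#' @param min_count minimum accepted applicants for a bin to count
#'   (default 10).
#' @param min_acceptance minimum per-bin acceptance rate for a bin to
#'   count (default 0.01).
#' @return an object of class `"completion_curve"`: data.frame with
#'   columns `bin`, `n_total`, `n_accepted`, `acceptance_rate`,
#'   `completion_rate`, `occupied`.
#' @export
completion_curve <- function(test_percentiles, mask, outcomes,
                             min_count = 10L, min_acceptance = 0.01) {
  stopifnot(inherits(mask, "acceptance_mask"))
  y <- if (inherits(outcomes, "completion_outcomes")) outcomes$outcome else
    outcomes
  stopifnot(length(test_percentiles) == length(mask$accepted),
            length(y) == length(mask$accepted))
  bin <- as.integer(ceiling(test_percentiles))
  bin[bin < 1L] <- 1L
  bin[bin > 100L] <- 100L
  lev <- 1:100
  n_total <- tabulate(bin, nbins = 100L)
  acc <- mask$accepted
  n_accepted <- tabulate(bin[acc], nbins = 100L)
  sum_y <- vapply(split(y[acc], factor(bin[acc], levels = lev)), sum,
                  numeric(1))
  acc_rate <- ifelse(n_total > 0, n_accepted / n_total, NA_real_)
  occupied <- n_accepted >= min_count &
    !is.na(acc_rate) & acc_rate >= min_acceptance
  rate <- ifelse(occupied, sum_y / n_accepted, NA_real_)
  out <- data.frame(
    bin = lev,
    n_total = n_total,
    n_accepted = n_accepted,
    acceptance_rate = acc_rate,
    completion_rate = rate,
    occupied = occupied
  )
  class(out) <- c("completion_curve", "data.frame")
  out
}

#' @export
print.completion_curve <- function(x, ...) {
  occ <- sum(x$occupied)
  cat(sprintf("Completion curve: %d of 100 test-percentile bins occupied\n",
              occ))
  if (occ >= 3L) {
    cc <- curve_correlation(x)
    cat(sprintf("  bin-vs-completion r = %.3f (p = %.3g), slope = %.4f/pctile\n",
                cc$r, cc$p, regression_slope(x)))
  }
  invisible(x)
}

#' Correlation between test-percentile bin and completion rate
#'
#' Pearson correlation over the occupied bins, each bin one equally
#' weighted observation (the plotted per-bin series, not the
#' individual-level outcomes), with the two-sided p-value from the
#' t-distribution on `bins - 2` degrees of freedom.
#'
#' @param curve a [completion_curve()].
#' @return list with `r`, `p`, and `n_bins`.
#' @export
curve_correlation <- function(curve) {
  stopifnot(inherits(curve, "completion_curve"))
  use <- curve$occupied & !is.na(curve$completion_rate)
  if (sum(use) < 3L) {
    stop("need at least 3 occupied bins for a correlation", call. = FALSE)
  }
  x <- curve$bin[use]
  y <- curve$completion_rate[use]
  if (stats::sd(y) == 0) {
    # flat curve: define r = 0, p = 1 rather than NA from cor.test
    return(list(r = 0, p = 1, n_bins = sum(use)))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n_bins = sum(use))
}

#' OLS slope of completion rate on test-percentile bin
#'
#' Ordinary least-squares slope of the per-bin completion proportion on
#' the bin center over occupied bins, in proportion-per-percentile units.
#' Multiply by 100 for percent-completion change per percentile (a slope
#' of 0.002 means a 10-percentile test increase corresponds to a 2
#' percentage-point higher completion rate).
#'
#' @param curve a [completion_curve()].
#' @param se logical; if `TRUE` return a list with `slope` and its
#'   standard error instead of the bare slope.
#' @return slope (proportion per percentile), or list(`slope`, `se`).
#' @export
regression_slope <- function(curve, se = FALSE) {
  stopifnot(inherits(curve, "completion_curve"))
  use <- curve$occupied & !is.na(curve$completion_rate)
  if (sum(use) < 3L) {
    stop("need at least 3 occupied bins for a slope", call. = FALSE)
  }
  fit <- stats::lm(completion_rate ~ bin, data = curve[use, ])
  if (!se) return(unname(stats::coef(fit)[2]))
  s <- summary(fit)$coefficients
  list(slope = unname(s[2, 1]), se = unname(s[2, 2]))
}

#' Correlation between Test and the other predictors among accepted
#'
#' The collider-bias diagnostic: the Pearson correlation, among accepted
#' applicants, between the Test percentile and the remaining predictors.
#' Two readings are returned: `r_sum`, the correlation of Test with the
#' unweighted SUM of the other predictors' percentiles (primary), and
#' `r_pairwise`, the mean of the pairwise correlations of Test with each
#' other predictor.
#'
#' @param panel a [build_predictors()] panel.
#' @param mask an `"acceptance_mask"`.
#' @param test name of the Test column.
#' @return list with `r_sum` and `r_pairwise`.
#' @export
test_vs_rest_correlation <- function(panel, mask, test = "Test") {
  stopifnot(inherits(panel, "predictor_panel"),
            inherits(mask, "acceptance_mask"))
  if (mask$n_accepted < 3L) stop("need >= 3 accepted", call. = FALSE)
  pc <- panel$percentiles[mask$accepted, , drop = FALSE]
  others <- setdiff(panel$predictor_names, test)
  tv <- pc[, test]
  rest <- pc[, others, drop = FALSE]
  if (stats::sd(tv) == 0) stop("degenerate test variance", call. = FALSE)
  list(
    r_sum = stats::cor(tv, rowSums(rest)),
    r_pairwise = mean(apply(rest, 2, function(col) stats::cor(tv, col)))
  )
}

#' Test-retest reliability of a percentile score
#'
#' Simulates the same individuals taking the same noisy test twice: one
#' latent signal per individual (a linear combination with weights
#' `loading_row`), two independent Normal(0, `noise_sd`) measurement
#' errors, each measurement percentile-ranked across individuals, and the
#' Pearson correlation of the two percentile vectors returned. With a
#' unit loading and unit noise the raw-score correlation is 0.5 and the
#' percentile correlation is `(6/pi) * asin(0.25) = 0.483` — a fairly low
#' reliability of about .48.
#'
#' @param loading_row numeric weight vector over the latent
#'   characteristics (default a single unit loading).
#' @param noise_sd measurement noise standard deviation (default 1).
#' @param n number of simulated individuals (>= 100).
#' @param seed root seed.
#' @return Pearson correlation of the two percentile vectors.
#' @export
test_retest_reliability <- function(loading_row = 1, noise_sd = 1,
                                    n = 1e6, seed = 1L) {
  if (n < 100) stop("need n >= 100 for a stable reliability", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  k <- length(loading_row)
  latents <- with_substream(seed, "retest:latents",
                            matrix(stats::rnorm(n * k), n, k))
  signal <- drop(latents %*% loading_row)
  m1 <- signal + with_substream(seed, "retest:noise1",
                                stats::rnorm(n, sd = noise_sd))
  m2 <- signal + with_substream(seed, "retest:noise2",
                                stats::rnorm(n, sd = noise_sd))
  p1 <- percentile_transform(m1, seed = seed, name = "retest1")
  p2 <- percentile_transform(m2, seed = seed, name = "retest2")
  stats::cor(p1, p2)
}

#' Full metrics report for one (cohort, policy) cell
#'
#' Bundles every summary reported per grid cell: the accepted completion
#' percentage, the binned acceptance/completion curves, the curve
#' correlation with its p-value and R^2, the OLS slope, and the
#' test-vs-others collider correlations.
#'
#' @param cohort a [simulate_cohort()] object.
#' @param mask an `"acceptance_mask"` for that cohort.
#' @param test name of the Test column.
#' @param min_count minimum accepted per bin (default 10).
#' @param min_acceptance minimum per-bin acceptance rate (default 0.01).
#' @return an object of class `"metrics_report"`.
#' @export
metrics_report <- function(cohort, mask, test = "Test", min_count = 10L,
                           min_acceptance = 0.01) {
  stopifnot(inherits(cohort, "compsel_cohort"),
            inherits(mask, "acceptance_mask"))
  curve <- completion_curve(cohort$panel$percentiles[, test], mask,
                            cohort$outcomes, min_count = min_count,
                            min_acceptance = min_acceptance)
  cc <- curve_correlation(curve)
  sl <- regression_slope(curve, se = TRUE)
  tvr <- test_vs_rest_correlation(cohort$panel, mask, test = test)
  structure(
    list(
      completion_pct = completion_rate(mask, cohort$outcomes),
      curve = curve,
      curve_r = cc$r, curve_p = cc$p, r_squared = cc$r^2,
      n_bins = cc$n_bins,
      slope = sl$slope, slope_se = sl$se,
      test_vs_rest_r = tvr$r_sum, test_vs_rest_r_pairwise = tvr$r_pairwise,
      n_accepted = mask$n_accepted
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  star <- if (x$curve_p < 0.001) "**" else ""
  cat(sprintf("Accepted completion: %.1f%%  (n accepted = %s)\n",
              x$completion_pct, format(x$n_accepted, big.mark = ",")))
  cat(sprintf("Curve r = %.3f%s (p = %.3g, %d bins), R^2 = %.2f\n",
              x$curve_r, star, x$curve_p, x$n_bins, x$r_squared))
  cat(sprintf("Slope = %.4f completion-proportion per percentile (%.2f%%/pctile)\n",
              x$slope, 100 * x$slope))
  cat(sprintf("Test vs other predictors among accepted: r = %.3f (sum), %.3f (mean pairwise)\n",
              x$test_vs_rest_r, x$test_vs_rest_r_pairwise))
  invisible(x)
}
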