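test_that("completion rate is the accepted-mean percentage", {
  out <- structure(list(probability = rep(1, 6), outcome = rep(1L, 6)),
                   class = "completion_outcomes")
  all_m <- structure(list(accepted = rep(TRUE, 6), n_accepted = 6L),
                     class = "acceptance_mask")
  expect_identical(completion_rate(all_m, out), 100)
  half <- structure(list(accepted = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
                         n_accepted = 3L), class = "acceptance_mask")
  expect_equal(completion_rate(half, c(1L, 0L, 1L, 1L, 0L, 1L)), 100 / 3)
  none <- structure(list(accepted = rep(FALSE, 6), n_accepted = 0L),
                    class = "acceptance_mask")
  expect_error(completion_rate(none, out), "no accepted")
})

test_that("population completion under accept-all matches the analytic 33.4%", {
  cfg <- sim_config(n_applicants = 2e5, seed = 17)
  coh <- simulate_cohort(cfg, ground_truth("invalid_test"))
  mask <- apply_policy(coh$panel, admissions_policy("accept_all"))
  tol <- 3 * 100 * sqrt(0.334 * 0.666 / cfg$n_applicants)
  expect_equal(completion_rate(mask, coh$outcomes), 33.4, tolerance = tol / 33.4)
  expect_lt(abs(completion_rate(mask, coh$outcomes) -
                  100 * expected_population_completion(cfg)), tol)
})

test_that("completion curve bins by ceiling with occupancy flags", {
  d <- make_linear_curve_data(bins = 10:40, slope = 0.002, intercept = 0.2,
                              m = 500)
  cv <- completion_curve(d$test_pct, d$mask, d$outcome, min_count = 10)
  expect_s3_class(cv, "completion_curve")
  expect_identical(nrow(cv), 100L)
  expect_identical(sum(cv$n_accepted), d$mask$n_accepted)
  occ <- cv$occupied
  expect_identical(cv$bin[occ], 10:40)
  expect_true(all(is.na(cv$completion_rate[!occ])))
  expect_equal(cv$completion_rate[occ], 0.2 + 0.002 * (10:40))
  expect_true(all(cv$acceptance_rate[occ] == 1))

  # flat independence case: every occupied bin near the global rate
  cfg <- sim_config(n_applicants = 1e5, seed = 19)
  coh <- simulate_cohort(cfg, ground_truth("invalid_test"))
  mask <- apply_policy(coh$panel, admissions_policy("accept_all"))
  cv2 <- completion_curve(coh$panel$percentiles[, "Test"], mask, coh$outcomes)
  g <- mean(coh$outcomes$outcome)
  dev <- abs(cv2$completion_rate - g)
  bound <- 5 * sqrt(g * (1 - g) / cv2$n_accepted)
  expect_true(all(dev[cv2$occupied] < bound[cv2$occupied]))

  # certain completion: every occupied bin at rate 1
  sure <- completion_curve(d$test_pct, d$mask, rep(1L, length(d$outcome)))
  expect_true(all(sure$completion_rate[sure$occupied] == 1))
})

test_that("curve correlation follows the covariance definition exactly", {
  d <- make_linear_curve_data(bins = 10:40, slope = 0.002, intercept = 0.2,
                              m = 500)
  cv <- completion_curve(d$test_pct, d$mask, d$outcome)
  cc <- curve_correlation(cv)
  # exactly linear rates: r = 1
  expect_equal(cc$r, 1, tolerance = 1e-12)
  expect_lt(cc$p, 1e-10)
  # brute-force covariance/sd identity on a noisy curve
  cfg <- sim_config(n_applicants = 5e4, seed = 23)
  coh <- simulate_cohort(cfg, ground_truth("valid_uncorrelated"))
  mask <- apply_policy(coh$panel, admissions_policy("weighted_sum",
                                                    fraction = 0.2), seed = 23)
  cv2 <- completion_curve(coh$panel$percentiles[, "Test"], mask, coh$outcomes)
  cc2 <- curve_correlation(cv2)
  use <- cv2$occupied
  expect_equal(cc2$r, brute_force_pearson(cv2$bin[use],
                                          cv2$completion_rate[use]),
               tolerance = 1e-12)
  # p-value from the t distribution with bins - 2 df
  tval <- cc2$r * sqrt((cc2$n_bins - 2) / (1 - cc2$r^2))
  expect_equal(cc2$p, 2 * pt(-abs(tval), cc2$n_bins - 2), tolerance = 1e-12)
  # flat curve: r defined as 0
  flat <- completion_curve(d$test_pct, d$mask, rep(1L, length(d$outcome)))
  expect_identical(curve_correlation(flat)$r, 0)
  expect_error(curve_correlation(cv2[0, ]), "occupied")
})

test_that("regression slope recovers a constructed linear relationship", {
  d <- make_linear_curve_data(bins = 10:40, slope = 0.002, intercept = 0.2,
                              m = 500)
  cv <- completion_curve(d$test_pct, d$mask, d$outcome)
  expect_equal(regression_slope(cv), 0.002, tolerance = 1e-12)
  # perfect fit by construction; summary.lm warns about it
  sl <- suppressWarnings(regression_slope(cv, se = TRUE))
  expect_equal(sl$slope, 0.002, tolerance = 1e-12)
  expect_lt(sl$se, 1e-10)
  # flat curve: slope within its own standard error of zero
  dflat <- make_linear_curve_data(bins = 10:40, slope = 0, intercept = 0.5,
                                  m = 10)
  set.seed(99)
  cvf <- completion_curve(dflat$test_pct, dflat$mask,
                          sample(dflat$outcome))
  slf <- regression_slope(cvf, se = TRUE)
  expect_lt(abs(slf$slope), 3 * slf$se + 1e-12)
})

test_that("test-vs-rest correlation distinguishes its two readings", {
  cfg <- sim_config(n_applicants = 1e5, seed = 29)
  coh <- simulate_cohort(cfg, ground_truth("invalid_test"))
  full <- apply_policy(coh$panel, admissions_policy("accept_all"))
  tv0 <- test_vs_rest_correlation(coh$panel, full)
  expect_lt(abs(tv0$r_sum), 3 / sqrt(cfg$n_applicants))
  expect_lt(abs(tv0$r_pairwise), 3 / sqrt(cfg$n_applicants))
  # both readings agree with direct computation among the accepted
  top <- apply_policy(coh$panel, admissions_policy("weighted_sum",
                                                   fraction = 0.1),
                      seed = 29)
  tv <- test_vs_rest_correlation(coh$panel, top)
  pc <- coh$panel$percentiles[top$accepted, ]
  expect_equal(tv$r_sum,
               brute_force_pearson(pc[, "Test"],
                                   pc[, "Grades"] + pc[, "Letters"] +
                                     pc[, "Statement"]),
               tolerance = 1e-12)
  expect_equal(tv$r_pairwise,
               mean(c(brute_force_pearson(pc[, "Test"], pc[, "Grades"]),
                      brute_force_pearson(pc[, "Test"], pc[, "Letters"]),
                      brute_force_pearson(pc[, "Test"], pc[, "Statement"]))),
               tolerance = 1e-12)
  expect_lt(tv$r_sum, 0)
  expect_lt(tv$r_pairwise, 0)
})

test_that("test-retest reliability matches the arcsine rank identity", {
  expect_equal(test_retest_reliability(noise_sd = 0, n = 500, seed = 1), 1,
               tolerance = 1e-12)
  expect_error(test_retest_reliability(n = 50), "n >= 100")
  n <- 2e5
  r <- test_retest_reliability(loading_row = 1, noise_sd = 1, n = n, seed = 31)
  # raw-score correlation is 1/2; percentile correlation (6/pi) asin(1/4)
  oracle <- (6 / pi) * asin(0.25)
  expect_equal(r, oracle, tolerance = 0.01 / oracle)
  expect_equal(r, 0.48, tolerance = 0.011 / 0.48)
})

test_that("metrics reports are deterministic and internally consistent", {
  cfg <- sim_config(n_applicants = 5e4, seed = 37)
  coh <- simulate_cohort(cfg, ground_truth("valid_uncorrelated"))
  mask <- apply_policy(coh$panel, admissions_policy("weighted_sum",
                                                    fraction = 0.1), seed = 37)
  rep1 <- metrics_report(coh, mask)
  rep2 <- metrics_report(coh, mask)
  expect_identical(rep1, rep2)
  expect_identical(rep1$r_squared, rep1$curve_r^2)
  expect_identical(sign(rep1$slope), sign(rep1$curve_r))
})

test_that("selection orders the curve correlations as expected", {
  # accept-all > compensatory top-10% > over-weighted top-10%
  cfg <- sim_config(n_applicants = 2e5, seed = 41)
  coh <- simulate_cohort(cfg, ground_truth("valid_uncorrelated"))
  r_all <- metrics_report(coh, apply_policy(coh$panel,
                                            admissions_policy("accept_all")))
  pol10 <- grid_policies(ground_truth("valid_uncorrelated"))$with_test
  r_10 <- metrics_report(coh, apply_policy(coh$panel, pol10, seed = 41))
  pol13 <- grid_policies(ground_truth("valid_uncorrelated_overweighted"))$with_test
  r_13 <- metrics_report(coh, apply_policy(coh$panel, pol13, seed = 41))
  expect_gt(r_all$curve_r, r_10$curve_r)
  expect_gt(r_10$curve_r, r_13$curve_r)
})
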