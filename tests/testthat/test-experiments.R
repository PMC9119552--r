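small_config <- function(n = 2e4, seed = 1, ...) {
  experiment_config(simulation = sim_config(n_applicants = n, seed = seed),
                    ...)
}

test_that("experiment configuration enforces its invariants", {
  cfg <- small_config()
  expect_identical(names(cfg$scenarios),
                   c("invalid_test", "valid_uncorrelated",
                     "valid_uncorrelated_overweighted", "valid_correlated"))
  expect_error(experiment_config(sweep_fractions = c(0.5, 0.5)),
               "strictly decreasing")
  expect_error(experiment_config(sweep_fractions = c(0.5, 1)),
               "strictly decreasing")
  dup <- default_scenarios()[c(1, 1)]
  expect_error(experiment_config(scenarios = dup), "unique")
})

test_that("the grid runs every scenario-policy cell on one shared cohort", {
  cfg <- small_config(seed = 7)
  grid <- run_figure1_grid(cfg, quiet = TRUE)
  expect_identical(nrow(grid$rows), 12L)
  expect_identical(length(grid$reports), 12L)
  expect_setequal(unique(grid$rows$policy),
                  c("accept_all", "with_test", "no_test"))
  # accept-all cells agree across scenarios within a shared MC band,
  # centred on the analytic population completion
  aa <- grid$rows[grid$rows$policy == "accept_all", "completion_pct"]
  target <- 100 * expected_population_completion(cfg$simulation)
  band <- 3 * 100 * sqrt(0.334 * 0.666 / cfg$simulation$n_applicants)
  expect_true(all(abs(aa - target) < band))
  # the uncorrelated scenarios share one cohort: accept-all cells identical
  expect_identical(
    grid$rows[grid$rows$scenario == "valid_uncorrelated" &
                grid$rows$policy == "accept_all", "completion_pct"],
    grid$rows[grid$rows$scenario == "valid_uncorrelated_overweighted" &
                grid$rows$policy == "accept_all", "completion_pct"])
  # deterministic replay
  grid2 <- run_figure1_grid(cfg, quiet = TRUE)
  expect_identical(grid$rows, grid2$rows)
  expect_identical(as.data.frame(grid), grid$rows)
})

test_that("the no-test policy is blind to the Test column's contents", {
  cfg <- sim_config(n_applicants = 2e4, seed = 3)
  coh_invalid <- simulate_cohort(cfg, ground_truth("invalid_test"))
  coh_valid <- simulate_cohort(cfg, ground_truth("valid_uncorrelated"))
  pol <- grid_policies(ground_truth("valid_uncorrelated"))$no_test
  m1 <- apply_policy(coh_invalid$panel, pol, seed = 3)
  m2 <- apply_policy(coh_valid$panel, pol, seed = 3)
  expect_identical(m1$accepted, m2$accepted)
  expect_identical(completion_rate(m1, coh_invalid$outcomes),
                   completion_rate(m2, coh_valid$outcomes))
})

test_that("cell metrics are stable across cohort sizes", {
  seeds <- 51
  scen <- ground_truth("invalid_test")
  pol <- grid_policies(scen)$with_test
  vals <- ses <- numeric(2)
  for (i in seq_along(c(2e4, 1e5))) {
    n <- c(2e4, 1e5)[i]
    coh <- simulate_cohort(sim_config(n_applicants = n, seed = seeds), scen)
    mask <- apply_policy(coh$panel, pol, seed = seeds)
    p <- completion_rate(mask, coh$outcomes) / 100
    vals[i] <- 100 * p
    ses[i] <- 100 * sqrt(p * (1 - p) / mask$n_accepted)
  }
  expect_lt(abs(vals[1] - vals[2]), 3 * sqrt(sum(ses^2)))
})

test_that("the selectivity sweep covers every scenario-fraction pair", {
  cfg <- small_config(n = 1e5, seed = 5)
  cfg$sweep_fractions <- seq(1, 0.1, by = -0.3)
  cfg$n_sweep <- 3e4
  sw <- run_selectivity_sweep(cfg, quiet = TRUE)
  expect_identical(nrow(sw$rows), 4L * length(cfg$sweep_fractions))
  expect_true(all(is.finite(sw$rows$slope_pct_per_percentile)))
  # fraction 1 means accept everyone: slope equals the accept-all slope
  coh <- simulate_cohort(sim_config(n_applicants = 3e4, seed = 5),
                         ground_truth("invalid_test"))
  all_mask <- apply_policy(coh$panel, admissions_policy("accept_all"))
  cv <- completion_curve(coh$panel$percentiles[, "Test"], all_mask,
                         coh$outcomes)
  expect_equal(
    sw$rows[sw$rows$scenario == "invalid_test" & sw$rows$fraction == 1,
            "slope_pct_per_percentile"],
    100 * regression_slope(cv), tolerance = 1e-9)
})

test_that("results round-trip to disk deterministically", {
  dir1 <- file.path(tempdir(), "compsel-out-a")
  dir2 <- file.path(tempdir(), "compsel-out-b")
  on.exit(unlink(c(dir1, dir2), recursive = TRUE), add = TRUE)
  cfg <- small_config(n = 1e4, seed = 2)
  grid <- run_figure1_grid(cfg, quiet = TRUE)
  files1 <- write_results(grid, dir1)
  expect_true(all(file.exists(files1)))
  got <- utils::read.csv(file.path(dir1, "grid.csv"))
  expect_identical(nrow(got), 12L)
  expect_identical(got$scenario, grid$rows$scenario)
  # byte-identical data files on rerun (manifest carries the timestamp)
  files2 <- write_results(run_figure1_grid(cfg, quiet = TRUE), dir2)
  for (f in c("grid.csv", "grid.json")) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))))
  }
  man <- jsonlite::read_json(file.path(dir1, "grid_manifest.json"))
  expect_identical(man$seed, 2L)
  expect_true(nzchar(man$timestamp))

  cfg$sweep_fractions <- c(1, 0.5, 0.1)
  cfg$n_sweep <- 1e4
  sw <- run_selectivity_sweep(cfg, quiet = TRUE)
  write_results(sw, dir1)
  expect_identical(nrow(utils::read.csv(file.path(dir1, "sweep.csv"))), 12L)
})

test_that("experiment configs parse from YAML with custom scenarios", {
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path), add = TRUE)
  writeLines(c(
    "simulation: {n_applicants: 5000, k_latents: 4, seed: 9}",
    "fraction: 0.2",
    "n_sweep: 2000",
    "sweep_fractions: [1.0, 0.5, 0.2]",
    "scenarios:",
    "  - name: invalid_test",
    "  - name: custom",
    "    loadings:",
    "      Test:      [1, 0, 0, 0]",
    "      Grades:    [0.58, 0.71, 0.41, 0]",
    "      Letters:   [0, 0.41, 0.71, 0.58]",
    "      Statement: [0, 0, 0, 1]",
    "    invalid: [Statement]",
    "    noise_sd: 0.5",
    "    test_weight: 1.3"
  ), path)
  cfg <- read_experiment_config(path)
  expect_identical(cfg$simulation$n_applicants, 5000)
  expect_identical(cfg$simulation$seed, 9L)
  expect_identical(cfg$fraction, 0.2)
  expect_identical(names(cfg$scenarios), c("invalid_test", "custom"))
  cust <- cfg$scenarios$custom
  expect_identical(cust$invalid_predictors, "Statement")
  expect_identical(cust$noise_sd, 0.5)
  expect_identical(cust$test_weight, 1.3)
  expect_equal(cust$loadings$matrix["Grades", ], c(0.58, 0.71, 0.41, 0),
               ignore_attr = TRUE)
  expect_output(validate_config(path), "Configuration OK")
  # policy block parsing
  pol <- parse_policy(list(type = "weighted_sum",
                           weights = list(Test = 1, Grades = 1, Letters = 1,
                                          Statement = 1),
                           fraction = 0.1))
  expect_s3_class(pol, "admissions_policy")
  expect_identical(pol$fraction, 0.1)
})

test_that("plot methods draw without error", {
  cfg <- small_config(n = 1e4, seed = 4)
  grid <- run_figure1_grid(cfg, quiet = TRUE)
  cfg$sweep_fractions <- c(1, 0.5, 0.1)
  cfg$n_sweep <- 1e4
  sw <- run_selectivity_sweep(cfg, quiet = TRUE)
  png_path <- tempfile(fileext = ".png")
  on.exit(unlink(png_path), add = TRUE)
  grDevices::png(png_path, width = 900, height = 900)
  expect_no_error(plot(grid))
  expect_no_error(plot(sw))
  grDevices::dev.off()
  expect_output(print(grid), "grid")
  expect_output(print(sw), "sweep")
})
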