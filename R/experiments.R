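#' Experiment configuration
#'
#' Bundles everything a full experiment needs: the simulation
#' configuration, the list of ground-truth scenarios (default: the four
#' canonical ones), the acceptance fraction of the selective policies,
#' the selectivity-sweep fractions, and the cohort size used per sweep
#' point (smaller than the grid cohort because the sweep runs 20
#' fractions per scenario).
#'
#' @param simulation a [sim_config()] (default `sim_config()`: 1e6
#'   applicants, 4 latents, seed 1).
#' @param scenarios named list of [ground_truth()] scenarios.
#' @param fraction acceptance fraction of the selective grid policies
#'   (default 0.1).
#' @param sweep_fractions strictly decreasing acceptance fractions in
#'   (0, 1] (default 1.00 down to 0.05 in 0.05 steps).
#' @param n_sweep applicants per sweep cohort (default 2e5).
#' @return an object of class `"experiment_config"`.
#' @export
experiment_config <- function(simulation = sim_config(),
                              scenarios = default_scenarios(),
                              fraction = 0.1,
                              sweep_fractions = seq(1, 0.05, by = -0.05),
                              n_sweep = 2e5) {
  stopifnot(inherits(simulation, "compsel_config"))
  if (!length(scenarios) || !all(vapply(scenarios, inherits, logical(1),
                                        "compsel_scenario"))) {
    stop("`scenarios` must be a list of ground_truth() scenarios",
         call. = FALSE)
  }
  if (is.null(names(scenarios))) {
    names(scenarios) <- vapply(scenarios, `[[`, character(1), "name")
  }
  if (anyDuplicated(names(scenarios))) {
    stop("scenario names must be unique", call. = FALSE)
  }
  if (any(sweep_fractions <= 0) || any(sweep_fractions > 1) ||
      any(diff(sweep_fractions) >= 0)) {
    stop("`sweep_fractions` must be strictly decreasing within (0, 1]",
         call. = FALSE)
  }
  structure(
    list(simulation = simulation, scenarios = scenarios,
         fraction = fraction, sweep_fractions = sweep_fractions,
         n_sweep = n_sweep),
    class = "experiment_config"
  )
}

#' The four canonical ground-truth scenarios
#'
#' @return named list: `invalid_test`, `valid_uncorrelated`,
#'   `valid_uncorrelated_overweighted`, `valid_correlated`.
#' @export
default_scenarios <- function() {
  nms <- c("invalid_test", "valid_uncorrelated",
           "valid_uncorrelated_overweighted", "valid_correlated")
  stats::setNames(lapply(nms, ground_truth), nms)
}

#' The three grid policies for a scenario
#'
#' Accept-everyone; top-`fraction` on the weighted sum of all four
#' predictor percentiles (the Test weight comes from the scenario, 1.3
#' for the over-weighted scenario); and top-`fraction` on the sum of the
#' non-test predictors (Test weight 0).
#'
#' @param scenario a [ground_truth()] scenario.
#' @param fraction acceptance fraction of the selective policies.
#' @return named list of [admissions_policy()] objects: `accept_all`,
#'   `with_test`, `no_test`.
#' @export
grid_policies <- function(scenario, fraction = 0.1) {
  w <- stats::setNames(rep(1, 4), default_predictors())
  w_with <- w; w_with["Test"] <- scenario$test_weight
  w_no <- w; w_no["Test"] <- 0
  list(
    accept_all = admissions_policy("accept_all", label = "accept all"),
    with_test = admissions_policy("weighted_sum", weights = w_with,
                                  fraction = fraction,
                                  label = sprintf("top %d%% with Test",
                                                  round(100 * fraction))),
    no_test = admissions_policy("weighted_sum", weights = w_no,
                                fraction = fraction,
                                label = sprintf("top %d%% without Test",
                                                round(100 * fraction)))
  )
}

#' Run the scenario-by-policy grid experiment
#'
#' For each ground-truth scenario, simulates ONE cohort and applies each
#' of the three policies (accept all, selective with test, selective
#' without test) to that same cohort, computing a full [metrics_report()]
#' per cell. Deterministic given the configuration seed.
#'
#' @param config an [experiment_config()].
#' @param quiet suppress per-cell progress messages.
#' @return an object of class `"compsel_grid"`: list with `rows` (one
#'   data.frame row per cell), `reports` (named list of
#'   [metrics_report()]s), and `provenance`.
#' @export
run_figure1_grid <- function(config = experiment_config(), quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- list()
  reports <- list()
  for (sname in names(config$scenarios)) {
    scenario <- config$scenarios[[sname]]
    t0 <- proc.time()[["elapsed"]]
    cohort <- simulate_cohort(config$simulation, scenario)
    policies <- grid_policies(scenario, config$fraction)
    for (pname in names(policies)) {
      cell <- paste(sname, pname, sep = ".")
      rep <- tryCatch({
        mask <- apply_policy(cohort$panel, policies[[pname]],
                             seed = config$simulation$seed)
        metrics_report(cohort, mask)
      }, error = function(e) {
        stop("grid cell '", cell, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
      reports[[cell]] <- rep
      rows[[cell]] <- data.frame(
        scenario = sname, policy = pname,
        completion_pct = rep$completion_pct,
        curve_r = rep$curve_r, curve_p = rep$curve_p,
        r_squared = rep$r_squared,
        slope_pct_per_percentile = 100 * rep$slope,
        test_vs_rest_r = rep$test_vs_rest_r,
        test_vs_rest_r_pairwise = rep$test_vs_rest_r_pairwise,
        n_accepted = rep$n_accepted
      )
      if (!quiet) {
        message(sprintf(
          "[grid] %-45s completion %5.1f%%  r %+.3f  (%.1fs)", cell,
          rep$completion_pct, rep$curve_r,
          proc.time()[["elapsed"]] - t0))
      }
      dropped <- sum(!reports[[cell]]$curve$occupied &
                       reports[[cell]]$curve$n_accepted > 0)
      if (!quiet && dropped > 0) {
        message(sprintf("[grid]   %d low-occupancy bins dropped from curve",
                        dropped))
      }
    }
  }
  structure(
    list(rows = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         reports = reports,
         provenance = provenance_record(config)),
    class = "compsel_grid"
  )
}

#' Run the selectivity sweep
#'
#' For each scenario, simulates one cohort of `n_sweep` applicants and
#' sweeps the acceptance fraction over `sweep_fractions` (the same cohort
#' reused across fractions), selecting on the with-test weighted sum
#' (test weight from the scenario) and recording the completion-curve
#' regression slope per point. Fraction 1 uses accept-all semantics.
#'
#' @param config an [experiment_config()].
#' @param quiet suppress progress messages.
#' @return an object of class `"compsel_sweep"`: list with `rows`
#'   (scenario, fraction, slope in percent per percentile, slope_se) and
#'   `provenance`.
#' @export
run_selectivity_sweep <- function(config = experiment_config(),
                                  quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  sim <- config$simulation
  sweep_sim <- sim_config(n_applicants = config$n_sweep,
                          k_latents = sim$k_latents, seed = sim$seed,
                          sufficiency_mean = sim$sufficiency_mean,
                          sufficiency_sd = sim$sufficiency_sd)
  rows <- list()
  for (sname in names(config$scenarios)) {
    scenario <- config$scenarios[[sname]]
    cohort <- simulate_cohort(sweep_sim, scenario)
    w <- stats::setNames(rep(1, 4), default_predictors())
    w["Test"] <- scenario$test_weight
    for (f in config$sweep_fractions) {
      policy <- if (f == 1) admissions_policy("accept_all") else
        admissions_policy("weighted_sum", weights = w, fraction = f)
      mask <- apply_policy(cohort$panel, policy, seed = sweep_sim$seed)
      curve <- completion_curve(cohort$panel$percentiles[, "Test"], mask,
                                cohort$outcomes)
      sl <- regression_slope(curve, se = TRUE)
      rows[[paste(sname, f)]] <- data.frame(
        scenario = sname, fraction = f,
        slope_pct_per_percentile = 100 * sl$slope,
        slope_se = 100 * sl$se
      )
    }
    if (!quiet) message(sprintf("[sweep] %s: %d fractions done", sname,
                                length(config$sweep_fractions)))
  }
  structure(
    list(rows = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         provenance = provenance_record(config, n = config$n_sweep)),
    class = "compsel_sweep"
  )
}

provenance_record <- function(config, n = config$simulation$n_applicants) {
  list(
    seed = config$simulation$seed,
    n_applicants = n,
    k_latents = config$simulation$k_latents,
    scenarios = names(config$scenarios),
    package_version = as.character(utils::packageVersion("compsel")),
    config_hash = substream_seed(0L, paste(deparse(unclass_deep(config)),
                                           collapse = ""))
  )
}

# strip classes recursively so deparse() of a config is stable
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

#' @export
print.compsel_grid <- function(x, ...) {
  cat("Scenario x policy grid (", nrow(x$rows), " cells, n = ",
      format(x$provenance$n_applicants, big.mark = ","), ", seed ",
      x$provenance$seed, ")\n", sep = "")
  df <- x$rows
  df$completion_pct <- round(df$completion_pct, 1)
  df$curve_r <- round(df$curve_r, 3)
  df$slope_pct_per_percentile <- round(df$slope_pct_per_percentile, 3)
  df$test_vs_rest_r <- round(df$test_vs_rest_r, 3)
  print(df[, c("scenario", "policy", "completion_pct", "curve_r",
               "slope_pct_per_percentile", "test_vs_rest_r")])
  invisible(x)
}

#' @export
print.compsel_sweep <- function(x, ...) {
  cat("Selectivity sweep (", nrow(x$rows), " points, n = ",
      format(x$provenance$n_applicants, big.mark = ","), " per cohort)\n",
      sep = "")
  for (s in unique(x$rows$scenario)) {
    sub <- x$rows[x$rows$scenario == s, ]
    cat(sprintf("  %-32s slope range [%+.3f, %+.3f] %%/percentile\n", s,
                min(sub$slope_pct_per_percentile),
                max(sub$slope_pct_per_percentile)))
  }
  invisible(x)
}

#' @export
as.data.frame.compsel_grid <- function(x, ...) x$rows

#' @export
as.data.frame.compsel_sweep <- function(x, ...) x$rows

#' Plot a grid result
#'
#' One panel per (scenario, policy) cell showing the per-test-percentile
#' acceptance rate (grey) and completion rate among accepted (black),
#' with the cell completion percentage and curve r annotated.
#'
#' @param x a `"compsel_grid"`.
#' @param ... unused.
#' @export
plot.compsel_grid <- function(x, ...) {
  cells <- names(x$reports)
  scen <- unique(x$rows$scenario)
  pol <- unique(x$rows$policy)
  op <- graphics::par(mfrow = c(length(scen), length(pol)),
                      mar = c(2.5, 2.5, 1.5, 0.5), mgp = c(1.5, 0.5, 0))
  on.exit(graphics::par(op))
  for (s in scen) for (p in pol) {
    cell <- paste(s, p, sep = ".")
    rep <- x$reports[[cell]]
    cv <- rep$curve
    graphics::plot(cv$bin, cv$acceptance_rate, type = "l", col = "grey60",
                   ylim = c(0, 1), xlab = "Test percentile", ylab = "rate",
                   main = cell, cex.main = 0.8)
    graphics::lines(cv$bin[cv$occupied], cv$completion_rate[cv$occupied],
                    lwd = 2)
    graphics::legend("bottomright", bty = "n", cex = 0.8, legend = sprintf(
      "%.1f%%  r=%.3f%s", rep$completion_pct, rep$curve_r,
      if (rep$curve_p < 0.001) "**" else ""))
  }
  invisible(x)
}

#' Plot a sweep result
#'
#' Regression slope (percent completion per test percentile) against the
#' acceptance percentage, one line per scenario, with reference lines at
#' slope 0 and 10% acceptance.
#'
#' @param x a `"compsel_sweep"`.
#' @param ... unused.
#' @export
plot.compsel_sweep <- function(x, ...) {
  scen <- unique(x$rows$scenario)
  cols <- seq_along(scen)
  graphics::plot(NULL, xlim = c(100, 5),
                 ylim = range(x$rows$slope_pct_per_percentile),
                 xlab = "Acceptance percentage",
                 ylab = "Slope (% completion / Test percentile)")
  graphics::abline(h = 0, lty = 3)
  graphics::abline(v = 10, lty = 2, col = "grey50")
  for (i in seq_along(scen)) {
    sub <- x$rows[x$rows$scenario == scen[i], ]
    graphics::lines(100 * sub$fraction, sub$slope_pct_per_percentile,
                    type = "b", pch = i, col = cols[i])
  }
  graphics::legend("bottomleft", legend = scen, col = cols, pch = cols,
                   cex = 0.8, bty = "n")
  invisible(x)
}

#' Write experiment results to disk
#'
#' Emits the canonical outputs for a grid or sweep result: a CSV with one
#' row per cell/point, a JSON file with the full reports (including the
#' per-bin curves for a grid), and a run manifest (seed, n, scenario
#' list, package version, config hash, timestamp). Reruns with the same
#' configuration produce byte-identical CSV and results JSON; only the
#' manifest timestamp differs.
#'
#' @param result a `"compsel_grid"` or `"compsel_sweep"`.
#' @param output_dir directory to write into (created if needed).
#' @return invisibly, a character vector of the files written.
#' @export
write_results <- function(result, output_dir) {
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(output_dir)) {
      stop("cannot create output directory: ", output_dir, call. = FALSE)
    }
  }
  kind <- if (inherits(result, "compsel_grid")) "grid" else if
    (inherits(result, "compsel_sweep")) "sweep" else
    stop("unsupported result type", call. = FALSE)
  csv <- file.path(output_dir, paste0(kind, ".csv"))
  jsn <- file.path(output_dir, paste0(kind, ".json"))
  man <- file.path(output_dir, paste0(kind, "_manifest.json"))
  utils::write.csv(result$rows, csv, row.names = FALSE)
  payload <- if (kind == "grid") {
    list(rows = result$rows,
         curves = lapply(result$reports, function(r)
           r$curve[r$curve$n_total > 0, ]))
  } else {
    list(rows = result$rows)
  }
  jsonlite::write_json(payload, jsn, dataframe = "rows", digits = NA,
                       na = "null", auto_unbox = TRUE)
  jsonlite::write_json(
    c(result$provenance, list(timestamp = format(Sys.time(), tz = "UTC"))),
    man, auto_unbox = TRUE)
  invisible(c(csv, jsn, man))
}
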