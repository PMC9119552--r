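#' Read an experiment configuration from YAML or JSON
#'
#' The file mirrors the constructor arguments:
#' ```yaml
#' simulation: {n_applicants: 1000000, k_latents: 4, seed: 1}
#' fraction: 0.10
#' n_sweep: 200000
#' sweep_fractions: [1.0, 0.95, 0.90]   # optional, default 1.00..0.05
#' scenarios:
#'   - name: invalid_test
#'   - name: custom
#'     loadings:
#'       Test:      [1, 0, 0, 0]
#'       Grades:    [0.58, 0.71, 0.41, 0]
#'       Letters:   [0, 0.41, 0.71, 0.58]
#'       Statement: [0, 0, 0, 1]
#'     invalid: [Test]
#'     noise_sd: 1.0
#'     test_weight: 1.0
#' ```
#' Omitted fields fall back to the package defaults; omitting `scenarios`
#' gives the four canonical ground truths.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  sim_args <- raw$simulation %||% list()
  simulation <- do.call(sim_config, sim_args)
  scenarios <- if (is.null(raw$scenarios)) default_scenarios() else
    lapply(raw$scenarios, parse_scenario)
  args <- list(simulation = simulation, scenarios = scenarios)
  if (!is.null(raw$fraction)) args$fraction <- raw$fraction
  if (!is.null(raw$sweep_fractions)) {
    args$sweep_fractions <- as.numeric(raw$sweep_fractions)
  }
  if (!is.null(raw$n_sweep)) args$n_sweep <- raw$n_sweep
  do.call(experiment_config, args)
}

parse_scenario <- function(s) {
  if (is.character(s)) s <- list(name = s)
  loadings <- NULL
  if (!is.null(s$loadings)) {
    m <- do.call(rbind, lapply(s$loadings, as.numeric))
    loadings <- factor_loadings(m, predictor_names = names(s$loadings))
  }
  ground_truth(
    name = s$name %||% "custom",
    loadings = loadings,
    invalid_predictors = as.character(s$invalid %||% character()),
    noise_sd = s$noise_sd %||% 1,
    test_weight = s$test_weight
  )
}

#' Parse a policy block from a configuration list
#'
#' Accepts the form
#' `policy: {type: weighted_sum, weights: {Test: 1.0, ...}, fraction: 0.10,
#' test_cutoff: 50}`.
#'
#' @param p named list as read from YAML/JSON.
#' @return an [admissions_policy()].
#' @export
parse_policy <- function(p) {
  admissions_policy(
    type = p$type %||% "weighted_sum",
    weights = if (!is.null(p$weights)) unlist(p$weights),
    fraction = p$fraction %||% 0.1,
    test_cutoff = p$test_cutoff %||% 50
  )
}

#' Validate an experiment configuration file
#'
#' Parses the file and reports the resulting configuration, including any
#' loading rows that violate the unit squared-weight constraint.
#'
#' @param path configuration file path.
#' @return the parsed [experiment_config()], invisibly.
#' @export
validate_config <- function(path) {
  cfg <- read_experiment_config(path)
  cat("Configuration OK:", path, "\n")
  print(cfg$simulation)
  for (s in cfg$scenarios) {
    rep <- validate_loadings(s$loadings)
    flag <- if (all(rep$ok)) "loadings ok" else paste(
      "loadings FLAGGED:", paste(rep$predictor[!rep$ok], collapse = ", "))
    cat(sprintf("  scenario %-34s %s\n", s$name, flag))
  }
  cat(sprintf("  grid fraction %.2f; sweep %d fractions at n = %s\n",
              cfg$fraction, length(cfg$sweep_fractions),
              format(cfg$n_sweep, big.mark = ",")))
  invisible(cfg)
}
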