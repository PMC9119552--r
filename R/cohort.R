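#' Simulate a full applicant cohort
#'
#' Runs the complete generative model for one ground truth: latent
#' characteristics, completion probabilities under the sufficiency
#' product rule, Bernoulli completion outcomes, and the observable
#' predictor panel. All stages draw from named substreams of the
#' configuration seed, so the same configuration yields the identical
#' cohort, and different policies can be compared on the same cohort.
#'
#' @param config a [sim_config()].
#' @param scenario a [ground_truth()] scenario.
#' @return an object of class `"compsel_cohort"`: list with `config`,
#'   `scenario`, `latents`, `panel`, `probability`, `outcomes`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_applicants = 2000, seed = 7),
#'                        ground_truth("valid_uncorrelated"))
#' coh
#' @export
simulate_cohort <- function(config, scenario) {
  stopifnot(inherits(config, "compsel_config"),
            inherits(scenario, "compsel_scenario"))
  if (ncol(scenario$loadings$matrix) != config$k_latents) {
    stop("scenario loadings expect ", ncol(scenario$loadings$matrix),
         " latents but the configuration has ", config$k_latents,
         call. = FALSE)
  }
  latents <- sample_latents(config)
  suff <- sufficiency_probability(latents, mean = config$sufficiency_mean,
                                  sd = config$sufficiency_sd)
  prob <- completion_probability(suff)
  outcomes <- sample_outcomes(prob, seed = config$seed)
  panel <- build_predictors(latents, scenario, seed = config$seed)
  structure(
    list(config = config, scenario = scenario, latents = latents,
         panel = panel, probability = prob, outcomes = outcomes),
    class = "compsel_cohort"
  )
}

#' @export
print.compsel_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %s applicants, scenario '%s'\n",
              format(x$config$n_applicants, big.mark = ","),
              x$scenario$name))
  cat(sprintf("  mean completion probability: %.3f (analytic: %.3f)\n",
              mean(x$probability), expected_population_completion(x$config)))
  cat(sprintf("  realized completion rate: %.3f\n", mean(x$outcomes$outcome)))
  invisible(x)
}

#' @export
summary.compsel_cohort <- function(object, ...) {
  pc <- stats::cor(object$panel$percentiles)
  cat(sprintf("Cohort of %s applicants under scenario '%s'\n",
              format(object$config$n_applicants, big.mark = ","),
              object$scenario$name))
  cat(sprintf("  completion: %.1f%% realized, %.1f%% analytic expectation\n",
              100 * mean(object$outcomes$outcome),
              100 * expected_population_completion(object$config)))
  cat("  predictor percentile correlations:\n")
  print(round(pc, 3))
  invisible(list(predictor_correlation = pc,
                 completion = mean(object$outcomes$outcome)))
}
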