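#' Simulation configuration
#'
#' Holds the population-level parameters of the generative model: the
#' number of applicants, the number of latent characteristics, the root
#' RNG seed, and the sufficiency model. Each applicant has `k_latents`
#' independent standard-normal latent characteristics; the probability
#' that a single characteristic is sufficient for degree completion is
#' `pnorm(latent, sufficiency_mean, sufficiency_sd)`, and the completion
#' probability is the product of the per-characteristic sufficiencies.
#' Compensatory selection requires at least two latent characteristics,
#' hence `k_latents >= 2`.
#'
#' @param n_applicants number of simulated applicants (default `1e6`).
#' @param k_latents number of latent characteristics (default 4).
#' @param seed integer root seed; all substreams derive from it.
#' @param sufficiency_mean mean of the sufficiency normal CDF (default -1).
#' @param sufficiency_sd standard deviation of the sufficiency CDF
#'   (default 1, must be positive).
#' @return an object of class `"compsel_config"`.
#' @examples
#' cfg <- sim_config(n_applicants = 1000, seed = 42)
#' cfg
#' @export
sim_config <- function(n_applicants = 1e6, k_latents = 4L, seed = 1L,
                       sufficiency_mean = -1, sufficiency_sd = 1) {
  n_applicants <- as.double(n_applicants)
  k_latents <- as.integer(k_latents)
  if (length(n_applicants) != 1L || !is.finite(n_applicants) ||
      n_applicants < 1 || n_applicants != floor(n_applicants)) {
    stop("`n_applicants` must be a positive integer", call. = FALSE)
  }
  if (length(k_latents) != 1L || is.na(k_latents) || k_latents < 2L) {
    stop("`k_latents` must be an integer >= 2: compensation requires at ",
         "least two latent characteristics", call. = FALSE)
  }
  if (!is.numeric(sufficiency_sd) || length(sufficiency_sd) != 1L ||
      !is.finite(sufficiency_sd) || sufficiency_sd <= 0) {
    stop("`sufficiency_sd` must be a positive number", call. = FALSE)
  }
  if (!is.numeric(sufficiency_mean) || length(sufficiency_mean) != 1L ||
      !is.finite(sufficiency_mean)) {
    stop("`sufficiency_mean` must be a finite number", call. = FALSE)
  }
  seed <- as.integer(seed)
  if (length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  structure(
    list(n_applicants = n_applicants, k_latents = k_latents, seed = seed,
         sufficiency_mean = sufficiency_mean, sufficiency_sd = sufficiency_sd),
    class = "compsel_config"
  )
}

#' @export
print.compsel_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  applicants: %s   latents: %d   seed: %d\n",
              format(x$n_applicants, big.mark = ",", scientific = FALSE),
              x$k_latents, x$seed))
  cat(sprintf("  sufficiency CDF: Normal(mean = %g, sd = %g)\n",
              x$sufficiency_mean, x$sufficiency_sd))
  invisible(x)
}

#' Sample latent characteristics
#'
#' Draws the `n_applicants` x `k_latents` matrix of independent
#' standard-normal latent characteristics from the `"latents"` substream
#' of the configuration's root seed. The same configuration always yields
#' the same matrix.
#'
#' @param config a [sim_config()] object.
#' @return numeric matrix with `n_applicants` rows and `k_latents` columns.
#' @examples
#' L <- sample_latents(sim_config(n_applicants = 100, seed = 1))
#' dim(L)
#' @export
sample_latents <- function(config) {
  stopifnot(inherits(config, "compsel_config"))
  n <- config$n_applicants
  k <- config$k_latents
  with_substream(config$seed, "latents",
                 matrix(stats::rnorm(n * k), nrow = n, ncol = k))
}

#' Sufficiency probability of a latent characteristic
#'
#' The probability that an applicant's level on one latent characteristic
#' is sufficient to complete the degree: the normal CDF with the given
#' mean and standard deviation evaluated at the latent value. With the
#' defaults (mean -1, sd 1), a latent value of -0.158 has sufficiency
#' 0.80 and a value of 0.282 has sufficiency 0.90.
#'
#' @param latent_value numeric vector or matrix of latent values.
#' @param mean mean of the sufficiency CDF (default -1).
#' @param sd standard deviation of the sufficiency CDF (default 1, > 0).
#' @return probabilities in (0, 1), same shape as `latent_value`.
#' @examples
#' sufficiency_probability(c(-0.158, 0.282))
#' @export
sufficiency_probability <- function(latent_value, mean = -1, sd = 1) {
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0) {
    stop("`sd` must be a positive number", call. = FALSE)
  }
  p <- stats::pnorm(latent_value, mean = mean, sd = sd)
  if (is.matrix(latent_value)) dim(p) <- dim(latent_value)
  p
}

#' Completion probability under the product rule
#'
#' The probability of degree completion is the product of the
#' per-characteristic sufficiency probabilities: an applicant fully
#' sufficient on every characteristic completes with certainty, and a
#' zero sufficiency on any single characteristic makes failure certain.
#' For sufficiencies (.8, .8, .9, .9) the completion probability is
#' .8 * .8 * .9 * .9 = 0.5184, i.e. .52 to two decimals.
#'
#' @param sufficiencies numeric vector of per-characteristic sufficiency
#'   probabilities, or a matrix with one applicant per row.
#' @return a single probability for a vector input, or one probability per
#'   row for a matrix input. Always `<= min(sufficiencies)`.
#' @examples
#' completion_probability(c(.8, .8, .9, .9))
#' @export
completion_probability <- function(sufficiencies) {
  if (!is.numeric(sufficiencies) || anyNA(sufficiencies) ||
      any(sufficiencies < 0) || any(sufficiencies > 1)) {
    stop("sufficiency probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (is.matrix(sufficiencies)) {
    out <- rep(1, nrow(sufficiencies))
    for (j in seq_len(ncol(sufficiencies))) out <- out * sufficiencies[, j]
    out
  } else {
    prod(sufficiencies)
  }
}

#' Draw binary completion outcomes
#'
#' Degree completion for each applicant is a Bernoulli draw with the
#' applicant's completion probability, representing influences on
#' completion that no application can capture. Draws come from the
#' `"outcome"` substream so they are reproducible and independent of any
#' other simulation stage.
#'
#' @param probabilities numeric vector of completion probabilities.
#' @param seed root seed (the outcome substream is derived from it), or
#'   `NULL` to draw from the caller's RNG state.
#' @return an object of class `"completion_outcomes"`: a list with
#'   `probability` and the 0/1 integer vector `outcome`.
#' @examples
#' out <- sample_outcomes(c(0, 1, .5, .5), seed = 1)
#' out$outcome[1:2]
#' @export
sample_outcomes <- function(probabilities, seed = NULL) {
  if (!is.numeric(probabilities) || anyNA(probabilities) ||
      any(probabilities < 0) || any(probabilities > 1)) {
    stop("completion probabilities must lie in [0, 1]", call. = FALSE)
  }
  n <- length(probabilities)
  outcome <- with_substream(seed, "outcome",
                            as.integer(stats::runif(n) < probabilities))
  structure(list(probability = probabilities, outcome = outcome),
            class = "completion_outcomes")
}

#' Expected population completion rate (analytic)
#'
#' The population mean completion probability under the sufficiency model
#' has a closed analytic form: for one standard-normal latent L,
#' E\[pnorm(L, mean, sd)\] is computed by one-dimensional quadrature of
#' the CDF against the standard-normal density, and independence of the
#' latents raises it to the power `k_latents`. With the defaults
#' (k = 4, mean = -1, sd = 1) this equals `pnorm(1/sqrt(2))^4 = 0.3341`,
#' the 33.4% accept-everyone completion rate. Serves as the analytic
#' oracle for the Monte-Carlo population mean.
#'
#' @param config a [sim_config()] object.
#' @return expected completion probability in (0, 1).
#' @examples
#' expected_population_completion(sim_config(n_applicants = 10))
#' @export
expected_population_completion <- function(config) {
  stopifnot(inherits(config, "compsel_config"))
  mu <- config$sufficiency_mean
  sd <- config$sufficiency_sd
  one <- stats::integrate(
    function(x) stats::pnorm(x, mean = mu, sd = sd) * stats::dnorm(x),
    lower = -Inf, upper = Inf, rel.tol = 1e-10
  )$value
  one^config$k_latents
}
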