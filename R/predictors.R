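#' Linear combination of latents under factor loadings
#'
#' Raw (pre-noise) predictor scores: `raw[i, p] = sum_j loadings[p, j] *
#' latents[i, j]`. With identity loadings the raw scores equal the
#' latents.
#'
#' @param latents numeric matrix, applicants x latents.
#' @param loadings a [factor_loadings()] object (or bare matrix).
#' @return numeric matrix, applicants x predictors, with predictor column
#'   names.
#' @examples
#' L <- matrix(c(-0.158, -0.158, 0.282, 0.282), nrow = 1)
#' linear_combination(L, correlated_loadings())
#' @export
linear_combination <- function(latents, loadings) {
  m <- if (inherits(loadings, "factor_loadings")) loadings$matrix else
    as.matrix(loadings)
  latents <- as.matrix(latents)
  if (ncol(latents) != ncol(m)) {
    stop("latents have ", ncol(latents), " columns but loadings expect ",
         ncol(m), call. = FALSE)
  }
  raw <- latents %*% t(m)
  colnames(raw) <- rownames(m)
  raw
}

#' Add measurement noise to raw scores
#'
#' Adds independent Normal(0, `noise_sd`) error to every cell; each
#' predictor column draws from its own `"noise:<predictor>"` substream so
#' that altering one predictor's pipeline leaves the others untouched.
#' `noise_sd = 0` returns the input unchanged (the noiseless limit).
#'
#' @param raw numeric matrix of raw scores with predictor column names.
#' @param noise_sd non-negative noise standard deviation.
#' @param seed root seed, or `NULL` to use the caller's RNG state.
#' @return matrix of the same shape.
#' @export
add_measurement_noise <- function(raw, noise_sd, seed = NULL) {
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || is.na(noise_sd) ||
      noise_sd < 0) {
    stop("`noise_sd` must be a non-negative number", call. = FALSE)
  }
  if (noise_sd == 0) return(raw)
  n <- nrow(raw)
  nms <- colnames(raw)
  if (is.null(nms)) nms <- paste0("P", seq_len(ncol(raw)))
  for (j in seq_len(ncol(raw))) {
    raw[, j] <- raw[, j] + with_substream(
      seed, paste0("noise:", nms[j]), stats::rnorm(n, sd = noise_sd))
  }
  raw
}

#' Percentile transform by rank
#'
#' Rank-orders the values across all individuals and returns
#' `100 * rank / n`, a percentile score in (0, 100]. Ties are broken by
#' an independent random key (the `"ties:<name>"` substream when a seed
#' is supplied), so degenerate inputs carry no ordering artifacts. The
#' transform is invariant to any strictly increasing transformation of
#' the input, and its marginal distribution is uniform on (0, 100] by
#' construction.
#'
#' @param values numeric vector, length >= 1.
#' @param seed root seed for the tie-break substream, or `NULL`.
#' @param name substream suffix identifying the column being ranked.
#' @return percentile vector in (0, 100].
#' @examples
#' percentile_transform(c(3.1, -2.0, 0.5))
#' @export
percentile_transform <- function(values, seed = NULL, name = "values") {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  if (anyNA(values)) stop("missing values cannot be ranked", call. = FALSE)
  n <- length(values)
  r <- with_substream(seed, paste0("ties:", name),
                      rank(values, ties.method = "random"))
  100 * r / n
}

#' Build the predictor panel for a scenario
#'
#' The observable application: for each valid predictor, the
#' latent-to-raw linear combination, additive measurement noise, and the
#' percentile transform; for each invalid predictor, percentiles drawn
#' Uniform(0, 100] independently of the latents (its own
#' `"invalid:<predictor>"` substream). The pre-rank noisy raw scores are
#' retained for diagnostics.
#'
#' @param latents matrix from [sample_latents()].
#' @param scenario a [ground_truth()] scenario.
#' @param seed root seed (typically the configuration seed).
#' @return an object of class `"predictor_panel"`: list with
#'   `percentiles` (applicants x predictors, in (0, 100]), `raw`, and
#'   `predictor_names`.
#' @export
build_predictors <- function(latents, scenario, seed = NULL) {
  stopifnot(inherits(scenario, "compsel_scenario"))
  raw <- linear_combination(latents, scenario$loadings)
  raw <- add_measurement_noise(raw, scenario$noise_sd, seed = seed)
  nms <- scenario$loadings$predictor_names
  pct <- matrix(NA_real_, nrow(raw), ncol(raw), dimnames = list(NULL, nms))
  n <- nrow(raw)
  for (j in seq_along(nms)) {
    if (nms[j] %in% scenario$invalid_predictors) {
      pct[, j] <- with_substream(seed, paste0("invalid:", nms[j]),
                                 100 * stats::runif(n))
      raw[, j] <- NA_real_
    } else {
      pct[, j] <- percentile_transform(raw[, j], seed = seed, name = nms[j])
    }
  }
  structure(list(percentiles = pct, raw = raw, predictor_names = nms),
            class = "predictor_panel")
}

#' @export
print.predictor_panel <- function(x, ...) {
  cat(sprintf("Predictor panel: %s applicants x %d predictors (%s)\n",
              format(nrow(x$percentiles), big.mark = ","),
              length(x$predictor_names),
              paste(x$predictor_names, collapse = ", ")))
  invisible(x)
}
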