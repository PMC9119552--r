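#' Default predictor names
#'
#' The four components of the simulated application, in canonical order:
#' standardized Test score, Grades, reference Letters, personal Statement.
#' @return character vector of length four.
#' @export
default_predictors <- function() c("Test", "Grades", "Letters", "Statement")

#' Factor-loading matrix
#'
#' Weights mapping latent characteristics (columns) to raw predictor
#' scores (rows). To keep predictor variances equal, each row's sum of
#' squared weights is constrained to 1 (checked to a tolerance of 0.02,
#' which accommodates loadings printed to two decimals).
#'
#' @param matrix numeric matrix, `k_predictors` x `k_latents`.
#' @param predictor_names labels for the rows (default
#'   [default_predictors()]).
#' @return an object of class `"factor_loadings"`.
#' @examples
#' factor_loadings(diag(4))
#' @export
factor_loadings <- function(matrix, predictor_names = default_predictors()) {
  matrix <- as.matrix(matrix)
  if (!is.numeric(matrix) || anyNA(matrix)) {
    stop("loadings must be a numeric matrix without missing values",
         call. = FALSE)
  }
  if (length(predictor_names) != nrow(matrix)) {
    stop("need one predictor name per loading row", call. = FALSE)
  }
  rownames(matrix) <- predictor_names
  structure(list(matrix = matrix, predictor_names = predictor_names),
            class = "factor_loadings")
}

#' @export
print.factor_loadings <- function(x, ...) {
  cat("Factor loadings (predictors x latents)\n")
  print(round(x$matrix, 3))
  rep <- validate_loadings(x)
  if (any(!rep$ok)) {
    cat("Rows off unit squared-weight norm:",
        paste(rep$predictor[!rep$ok], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Identity loadings
#'
#' One-to-one correspondence between predictors and latent
#' characteristics: Test measures only the first latent, Grades the
#' second, and so on. Used by the uncorrelated-predictor scenarios.
#'
#' @param k number of predictors/latents (default 4).
#' @param predictor_names row labels.
#' @return a [factor_loadings()] object.
#' @export
identity_loadings <- function(k = 4L, predictor_names = default_predictors()) {
  factor_loadings(diag(k), predictor_names[seq_len(k)])
}

#' Correlated-predictor loadings
#'
#' The loading pattern of the valid-correlated scenario: Test and
#' Statement each measure a single latent, while Grades and Letters blend
#' neighbouring latents (rows approximately unit squared-weight norm).
#' With unit measurement noise this induces a percentile correlation of
#' about .28 between each adjacent predictor pair (Test-Grades,
#' Grades-Letters, Letters-Statement).
#'
#' @return a [factor_loadings()] object.
#' @examples
#' correlated_loadings()
#' @export
correlated_loadings <- function() {
  m <- rbind(
    Test      = c(1,   0,   0,   0),
    Grades    = c(.58, .71, .41, 0),
    Letters   = c(0,   .41, .71, .58),
    Statement = c(0,   0,   0,   1)
  )
  factor_loadings(m)
}

#' Validate loading rows against the unit squared-weight constraint
#'
#' Report-only check that each row's sum of squared weights is 1 within
#' `tol`. Rows printed to two decimals (e.g. .58/.71/.41 summing to
#' 1.0086) pass at the default tolerance.
#'
#' @param loadings a [factor_loadings()] object or bare matrix.
#' @param tol allowed deviation of the squared-weight sum from 1
#'   (default 0.02).
#' @return data.frame with columns `predictor`, `sq_sum`, `ok`.
#' @examples
#' validate_loadings(correlated_loadings())
#' @export
validate_loadings <- function(loadings, tol = 0.02) {
  m <- if (inherits(loadings, "factor_loadings")) loadings$matrix else
    as.matrix(loadings)
  sq <- rowSums(m^2)
  nms <- rownames(m)
  if (is.null(nms)) nms <- paste0("P", seq_len(nrow(m)))
  data.frame(predictor = nms, sq_sum = sq, ok = abs(sq - 1) <= tol,
             row.names = NULL)
}

#' Ground-truth scenarios
#'
#' A ground truth fixes what the observable predictors actually measure:
#' \describe{
#'   \item{`invalid_test`}{Test percentiles are uniform random draws,
#'     unrelated to any latent; the other three predictors each measure
#'     their own latent (identity loadings) plus unit noise.}
#'   \item{`valid_uncorrelated`}{all four predictors measure their own
#'     latent (identity loadings); predictors are mutually uncorrelated.}
#'   \item{`valid_uncorrelated_overweighted`}{the same generative model
#'     as `valid_uncorrelated`; the scenario carries a default admissions
#'     test weight of 1.3 so that selection over-weights the test.}
#'   \item{`valid_correlated`}{predictors blend latents via
#'     [correlated_loadings()], inducing ~.28 correlations between
#'     adjacent predictor percentiles.}
#' }
#'
#' @param name scenario name (see above), or `"custom"` with explicit
#'   `loadings`/`invalid_predictors`.
#' @param loadings optional [factor_loadings()] override.
#' @param invalid_predictors labels whose percentiles are replaced by
#'   Uniform(0, 100] draws independent of the latents.
#' @param noise_sd standard deviation of the measurement noise added to
#'   every raw predictor score (default 1).
#' @param test_weight default admissions weight for the Test predictor in
#'   this scenario's with-test policy (1.3 for the over-weighted
#'   scenario, 1 otherwise).
#' @return an object of class `"compsel_scenario"`.
#' @examples
#' ground_truth("invalid_test")
#' ground_truth("valid_correlated")
#' @export
ground_truth <- function(name = c("invalid_test", "valid_uncorrelated",
                                  "valid_uncorrelated_overweighted",
                                  "valid_correlated", "custom"),
                         loadings = NULL, invalid_predictors = character(),
                         noise_sd = 1, test_weight = NULL) {
  name <- match.arg(name)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("`noise_sd` must be a non-negative number", call. = FALSE)
  }
  if (is.null(loadings)) {
    loadings <- switch(name,
      valid_correlated = correlated_loadings(),
      custom = stop("`custom` scenarios need explicit `loadings`",
                    call. = FALSE),
      identity_loadings()
    )
  }
  stopifnot(inherits(loadings, "factor_loadings"))
  if (name == "invalid_test") {
    invalid_predictors <- union(invalid_predictors, "Test")
  }
  bad <- setdiff(invalid_predictors, loadings$predictor_names)
  if (length(bad)) {
    stop("unknown invalid predictors: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(test_weight)) {
    test_weight <- if (name == "valid_uncorrelated_overweighted") 1.3 else 1
  }
  structure(
    list(name = name, loadings = loadings,
         invalid_predictors = invalid_predictors, noise_sd = noise_sd,
         test_weight = test_weight),
    class = "compsel_scenario"
  )
}

#' @export
print.compsel_scenario <- function(x, ...) {
  cat("Ground-truth scenario:", x$name, "\n")
  if (length(x$invalid_predictors)) {
    cat("  invalid predictors (uniform percentiles):",
        paste(x$invalid_predictors, collapse = ", "), "\n")
  }
  cat(sprintf("  measurement noise sd: %g   default test weight: %g\n",
              x$noise_sd, x$test_weight))
  invisible(x)
}

#' Analytic percentile correlation between two predictors
#'
#' Closed-form oracle for the Monte-Carlo correlation between two
#' percentile-ranked predictor columns. Raw noisy scores are jointly
#' normal, with Pearson correlation
#' `rho = (L L')_pq / sqrt((|L_p|^2 + s^2) (|L_q|^2 + s^2))`
#' for loading rows `L_p`, `L_q` and noise sd `s`. Rank (hence
#' percentile) correlation of a bivariate normal follows the arcsine
#' identity `(6/pi) * asin(rho / 2)`. Predictors with uniform (invalid)
#' percentiles are independent of everything, so the correlation is 0,
#' flagged in the result.
#'
#' @param loadings a [factor_loadings()] object.
#' @param noise_sd measurement noise standard deviation.
#' @param p,q predictor labels or row indices.
#' @param invalid_predictors labels treated as invalid (correlation 0).
#' @return list with `raw` (Pearson correlation of the noisy raw scores),
#'   `percentile` (rank correlation), and `invalid` flag.
#' @examples
#' expected_percentile_correlation(correlated_loadings(), 1, "Test", "Grades")
#' @export
expected_percentile_correlation <- function(loadings, noise_sd, p, q,
                                            invalid_predictors = character()) {
  stopifnot(inherits(loadings, "factor_loadings"))
  m <- loadings$matrix
  idx <- function(lab) {
    if (is.character(lab)) match(lab, loadings$predictor_names) else
      as.integer(lab)
  }
  i <- idx(p); j <- idx(q)
  if (is.na(i) || is.na(j)) stop("unknown predictor", call. = FALSE)
  labs <- loadings$predictor_names[c(i, j)]
  if (any(labs %in% invalid_predictors)) {
    return(list(raw = 0, percentile = 0, invalid = TRUE))
  }
  rho <- sum(m[i, ] * m[j, ]) /
    sqrt((sum(m[i, ]^2) + noise_sd^2) * (sum(m[j, ]^2) + noise_sd^2))
  list(raw = rho, percentile = (6 / pi) * asin(rho / 2), invalid = FALSE)
}
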