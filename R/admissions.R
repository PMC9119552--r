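#' Admissions policy
#'
#' Defines who gets accepted:
#' \describe{
#'   \item{`accept_all`}{everyone is accepted (the no-selection baseline).}
#'   \item{`weighted_sum`}{applicants are ranked by a weighted sum of the
#'     predictor percentiles and the top `fraction` are accepted. Default
#'     weights are 1 per predictor; a test weight of 1.3 over-weights the
#'     test, a test weight of 0 drops it from the decision.}
#'   \item{`cutoff_blind`}{applicants below `test_cutoff` on the Test
#'     percentile are eliminated; survivors are ranked on the weighted
#'     sum of the NON-test predictors (the committee never sees the test
#'     score, only that the minimum was met).}
#'   \item{`cutoff_visible`}{same elimination, but survivors are ranked on
#'     the weighted sum including the Test, so the committee can still use
#'     the score compensatorily above the cutoff.}
#' }
#'
#' @param type policy type (see above).
#' @param weights named non-negative weights, one per predictor (default
#'   1 each).
#' @param fraction acceptance fraction in (0, 1] (default 0.1, the top
#'   10%). Ignored by `accept_all`.
#' @param test_cutoff Test-percentile threshold in \[0, 100\] for the
#'   cutoff policies (default 50).
#' @param label optional display label.
#' @return an object of class `"admissions_policy"`.
#' @examples
#' admissions_policy("weighted_sum", fraction = 0.1)
#' admissions_policy("weighted_sum", weights = c(Test = 0, Grades = 1,
#'   Letters = 1, Statement = 1))
#' @export
admissions_policy <- function(type = c("accept_all", "weighted_sum",
                                       "cutoff_blind", "cutoff_visible"),
                              weights = NULL, fraction = 0.1,
                              test_cutoff = 50, label = NULL) {
  type <- match.arg(type)
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, 4), default_predictors())
  }
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("`weights` must be named by predictor", call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights must be finite and non-negative", call. = FALSE)
  }
  if (type %in% c("cutoff_blind", "cutoff_visible")) {
    if (!is.numeric(test_cutoff) || length(test_cutoff) != 1L ||
        is.na(test_cutoff) || test_cutoff < 0 || test_cutoff > 100) {
      stop("cutoff policies need a `test_cutoff` in [0, 100]", call. = FALSE)
    }
  }
  structure(
    list(type = type, weights = weights, fraction = fraction,
         test_cutoff = test_cutoff, label = label %||% type),
    class = "admissions_policy"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.admissions_policy <- function(x, ...) {
  cat("Admissions policy:", x$label, "\n")
  if (x$type != "accept_all") {
    cat(sprintf("  acceptance fraction: %g\n", x$fraction))
    cat("  weights:", paste(sprintf("%s=%g", names(x$weights), x$weights),
                            collapse = ", "), "\n")
    if (x$type %in% c("cutoff_blind", "cutoff_visible")) {
      cat(sprintf("  test cutoff: %g (committee %s the score)\n",
                  x$test_cutoff,
                  if (x$type == "cutoff_blind") "never sees" else "sees"))
    }
  }
  invisible(x)
}

#' Weighted composite score
#'
#' `score[i] = sum_p w_p * percentile[i, p]` over the policy's weights.
#' A weight of zero removes that predictor from the decision.
#'
#' @param panel a [build_predictors()] panel.
#' @param weights named weight vector covering every predictor it names.
#' @return numeric score vector, one per applicant.
#' @examples
#' pan <- structure(list(percentiles = cbind(Test = 50, Grades = 50,
#'   Letters = 50, Statement = 50),
#'   predictor_names = default_predictors()), class = "predictor_panel")
#' composite_score(pan, c(Test = 1, Grades = 1, Letters = 1, Statement = 1))
#' @export
composite_score <- function(panel, weights) {
  stopifnot(inherits(panel, "predictor_panel"))
  missing <- setdiff(names(weights), panel$predictor_names)
  if (length(missing)) {
    stop("weights name unknown predictors: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(panel$predictor_names, names(weights))
  if (length(absent)) {
    stop("no weight given for: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  w <- weights[panel$predictor_names]
  drop(panel$percentiles %*% w)
}

#' Select the top fraction of scores
#'
#' Accepts exactly `floor(fraction * n)` applicants with the highest
#' scores (at least one). Ties at the boundary are broken by a random key
#' from the `"selection"` substream, so nested selectivities are
#' consistent: the top-5% set is a subset of the top-10% set for the same
#' scores and seed.
#'
#' @param scores numeric score vector.
#' @param fraction acceptance fraction in (0, 1].
#' @param seed root seed for the tie-break key, or `NULL`.
#' @return an object of class `"acceptance_mask"`: list with logical
#'   `accepted` and integer `n_accepted`.
#' @examples
#' select_top_fraction(1:10, 0.3, seed = 1)$accepted
#' @export
select_top_fraction <- function(scores, fraction, seed = NULL) {
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  n <- length(scores)
  k <- max(1L, as.integer(floor(fraction * n)))
  if (fraction == 1) {
    return(structure(list(accepted = rep(TRUE, n), n_accepted = n),
                     class = "acceptance_mask"))
  }
  key <- with_substream(seed, "selection", stats::runif(n))
  ord <- order(scores, key, decreasing = TRUE)
  accepted <- logical(n)
  accepted[ord[seq_len(k)]] <- TRUE
  structure(list(accepted = accepted, n_accepted = k),
            class = "acceptance_mask")
}

#' @export
print.acceptance_mask <- function(x, ...) {
  cat(sprintf("Acceptance mask: %s of %s accepted (%.1f%%)\n",
              format(x$n_accepted, big.mark = ","),
              format(length(x$accepted), big.mark = ","),
              100 * x$n_accepted / length(x$accepted)))
  invisible(x)
}

#' Apply an admissions policy to a predictor panel
#'
#' Dispatches on the policy type. For the cutoff policies the number
#' accepted is still `floor(fraction * n)` of the FULL applicant pool;
#' if fewer applicants survive the cutoff than that, the policy is
#' infeasible and an error is raised.
#'
#' @param panel a [build_predictors()] panel.
#' @param policy an [admissions_policy()].
#' @param seed root seed for tie-break keys.
#' @param test name of the Test predictor column (default `"Test"`).
#' @return an `"acceptance_mask"`.
#' @export
apply_policy <- function(panel, policy, seed = NULL, test = "Test") {
  stopifnot(inherits(panel, "predictor_panel"),
            inherits(policy, "admissions_policy"))
  n <- nrow(panel$percentiles)
  if (policy$type == "accept_all") {
    return(structure(list(accepted = rep(TRUE, n), n_accepted = n),
                     class = "acceptance_mask"))
  }
  if (policy$type == "weighted_sum") {
    scores <- composite_score(panel, policy$weights)
    return(select_top_fraction(scores, policy$fraction, seed = seed))
  }
  # cutoff policies: eliminate below-threshold test scores first
  survives <- panel$percentiles[, test] > policy$test_cutoff
  k <- max(1L, as.integer(floor(policy$fraction * n)))
  if (sum(survives) < k) {
    stop("infeasible policy: only ", sum(survives), " applicants exceed the ",
         "test cutoff but ", k, " acceptances are required", call. = FALSE)
  }
  w <- policy$weights
  if (policy$type == "cutoff_blind") w[test] <- 0
  scores <- composite_score(panel, w)
  key <- with_substream(seed, "selection", stats::runif(n))
  ord <- order(survives, scores, key, decreasing = TRUE)
  accepted <- logical(n)
  accepted[ord[seq_len(k)]] <- TRUE
  structure(list(accepted = accepted, n_accepted = k),
            class = "acceptance_mask")
}
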