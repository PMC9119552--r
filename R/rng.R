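#' Named random substreams from a single root seed
#'
#' Every stochastic stage of the simulator (latent draws, per-predictor
#' measurement noise, tie-break keys, Bernoulli outcomes, selection
#' tie-breaks) draws from its own named substream derived from one root
#' seed. Changing what one stage consumes therefore never perturbs another
#' stage's draws, which is what makes cross-policy comparisons on the same
#' simulated cohort meaningful: the no-test policy column of a grid is
#' bit-identical whether the test column is valid or replaced by uniform
#' noise.
#'
#' The substream seed is a deterministic mix of the root seed and a
#' polynomial hash of the stream name, reduced modulo 2^31 - 1.
#'
#' @param seed integer root seed.
#' @param name character scalar naming the stream, e.g. `"latents"`,
#'   `"noise:Test"`.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, name) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- (as.double(seed) %% m + m) %% m
  for (code in utf8ToInt(name)) {
    # h stays < 2^31 so 31*h + code < 2^36 is exact in doubles
    h <- (31 * h + code) %% m
  }
  as.integer(h)
}

#' Evaluate an expression under a named substream
#'
#' Seeds the Mersenne-Twister generator with [substream_seed()], evaluates
#' `expr`, and restores the caller's RNG state on exit, so package
#' internals never disturb user-level random number generation.
#'
#' @inheritParams substream_seed
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_substream <- function(seed, name, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(substream_seed(seed, name))
  }
  expr
}
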