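# shared test helpers: independent brute-force oracles and tiny builders

# Pearson correlation from first principles (independent of stats::cor.test)
brute_force_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  cv <- sum((x - mx) * (y - my)) / (n - 1)
  sx <- sqrt(sum((x - mx)^2) / (n - 1))
  sy <- sqrt(sum((y - my)^2) / (n - 1))
  cv / (sx * sy)
}

# a predictor panel with given percentile columns, bypassing simulation
make_panel <- function(...) {
  pct <- cbind(...)
  structure(list(percentiles = pct, raw = pct,
                 predictor_names = colnames(pct)),
            class = "predictor_panel")
}

# a completion curve with exactly linear per-bin rates: for bins 1..k,
# rate = intercept + slope*bin, realized exactly by m trials per bin
make_linear_curve_data <- function(bins, slope, intercept, m) {
  stopifnot(all(abs(m * (intercept + slope * bins) -
                      round(m * (intercept + slope * bins))) < 1e-9))
  test_pct <- rep(bins, each = m)
  y <- unlist(lapply(bins, function(b) {
    k <- round(m * (intercept + slope * b))
    c(rep(1L, k), rep(0L, m - k))
  }))
  list(test_pct = test_pct, outcome = y,
       mask = structure(list(accepted = rep(TRUE, length(y)),
                             n_accepted = length(y)),
                        class = "acceptance_mask"))
}
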