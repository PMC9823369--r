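# Independent brute-force oracle for the stationary autocovariance:
# double loop over all pairs, biased (1/N) or unbiased (1/(N-j))
# normalization, sample-mean centring.
brute_force_acov <- function(x, max_lag_j, estimator = "biased") {
  n <- length(x)
  xb <- mean(x)
  vapply(0:max_lag_j, function(j) {
    s <- 0
    for (t in seq_len(n - j)) {
      s <- s + (x[t + j] - xb) * (x[t] - xb)
    }
    s / if (estimator == "biased") n else (n - j)
  }, numeric(1))
}

# Coarse deterministic grid-search oracle for the damped-cosine fit:
# minimizes the residual sum of squares of A*exp(-g*tau)*cos(w*tau)
# over a (g, w) grid with A profiled by linear least squares.
grid_search_damped_cosine <- function(tau, y, g_grid, w_grid) {
  best <- list(rss = Inf)
  for (g in g_grid) {
    for (w in w_grid) {
      basis <- exp(-g * tau) * cos(w * tau)
      A <- sum(basis * y) / sum(basis^2)
      rss <- sum((y - A * basis)^2)
      if (rss < best$rss) best <- list(rss = rss, A = A, g = g, w = w)
    }
  }
  best
}

control_params <- function() oscillator_params(k = 12e-9, gamma = 3, omega = 6)
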