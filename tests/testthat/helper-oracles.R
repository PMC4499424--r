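# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: dense integration via pracma::trapz on the
# piecewise-linear interpolant, OLS via explicit normal equations, and
# grouped summaries via explicit sum formulas.

dense_auc_oracle <- function(times, conc, n_sub = 1e4) {
  grid <- sort(unique(c(seq(min(times), max(times), length.out = n_sub + 1),
                        times)))
  pracma::trapz(grid, approx(times, conc, xout = grid)$y)
}

ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

group_stats_oracle <- function(values) {
  n <- length(values)
  m <- sum(values) / n
  s <- sqrt(sum((values - m)^2) / (n - 1))
  c(mean = m, sd = s, rsd = 100 * s / m)
}

random_profile_points <- function(n = 8) {
  t <- sort(runif(n, 0, 48))
  t <- t[c(TRUE, diff(t) > 1e-6)]
  list(times = t, conc = runif(length(t), 0.5, 1000))
}
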