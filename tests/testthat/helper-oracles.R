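# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Exhaustive grid search over (A, K) for the rectangular hyperbola fit.
grid_search_hyperbola <- function(t, y, n_grid = 200) {
  a_grid <- seq(0, 3 * max(y), length.out = n_grid)
  k_grid <- seq(0.01, 30, length.out = n_grid)
  best <- Inf
  for (a in a_grid) {
    # vectorise over k for speed
    pred <- outer(t, k_grid, function(tt, kk) a * tt / (tt + kk))
    rss <- colSums((y - pred)^2)
    m <- min(rss)
    if (m < best) best <- m
  }
  best
}

# Brute-force Monte-Carlo estimate of the Dunnett adjusted p-value for a
# balanced many-to-one design, by simulating the null sampling distribution
# of max |t| directly from group data (vectorised over simulations).
mc_dunnett_p <- function(t_obs, k, n_per_group, n_sims = 4e5) {
  n <- n_per_group
  df <- k * n - k
  means <- matrix(NA_real_, n_sims, k)
  ssw <- numeric(n_sims)
  for (g in seq_len(k)) {
    x <- matrix(rnorm(n * n_sims), nrow = n)
    m <- colMeans(x)
    means[, g] <- m
    ssw <- ssw + colSums(x^2) - n * m^2
  }
  s2 <- ssw / df
  tt <- (means[, -1, drop = FALSE] - means[, 1]) / sqrt(s2 * 2 / n)
  maxt <- apply(abs(tt), 1, max)
  mean(maxt >= abs(t_obs))
}

# From-scratch Conover-Iman t statistics (no ties assumed), following the
# rank-mean / pooled-rank-variance definition directly.
conover_oracle <- function(y, g, i, j) {
  r <- rank(y)
  N <- length(y)
  k <- length(unique(g))
  n <- tapply(r, g, length)
  rbar <- tapply(r, g, mean)
  s2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  h <- (sum(n * rbar^2) - N * (N + 1)^2 / 4) / s2
  se <- sqrt(s2 * (N - 1 - h) / (N - k) * (1 / n[[i]] + 1 / n[[j]]))
  (rbar[[i]] - rbar[[j]]) / se
}
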