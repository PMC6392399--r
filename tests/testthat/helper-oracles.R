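# Independent oracles used across the suite.  These deliberately avoid the
# package's computational paths (no log-sum-exp, no C++, no vectorized
# shortcuts) so agreement is informative.

# Conditional-logit log-likelihood by direct probability enumeration.
oracle_loglik <- function(X, set_id, used_row, set_animal, B) {
  total <- 0
  for (s in sort(unique(set_id))) {
    rows <- which(set_id == s)
    b <- B[set_animal[s], ]
    u <- as.vector(X[rows, , drop = FALSE] %*% b)
    p <- exp(u) / sum(exp(u))
    total <- total + log(p[rows == used_row[s]])
  }
  total
}

# Textbook potential scale reduction factor, written with explicit loops.
oracle_rhat <- function(draws) {
  m <- ncol(draws); n <- nrow(draws)
  means <- numeric(m); vars <- numeric(m)
  for (j in seq_len(m)) {
    means[j] <- sum(draws[, j]) / n
    vars[j] <- sum((draws[, j] - means[j])^2) / (n - 1)
  }
  grand <- sum(means) / m
  B <- n / (m - 1) * sum((means - grand)^2)
  W <- sum(vars) / m
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Quantile by explicit sort-and-interpolate (type-7 definition).
oracle_quantile <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * q + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Dense-grid posterior mean of the population mean mu for a 1-variable
# hierarchical conditional logit: integrates the individual coefficients on
# a beta grid, then (mu, sigma) on a 2-D grid.  Everything by direct
# exponentiation.
oracle_grid_posterior_mu <- function(X, set_id, used_row, set_animal,
                                     prior, mu_grid, sigma_grid, beta_grid) {
  animals <- sort(unique(set_animal))
  db <- beta_grid[2] - beta_grid[1]
  # per-animal data log-likelihood on the beta grid
  ll <- matrix(0, length(animals), length(beta_grid))
  for (ai in seq_along(animals)) {
    sets <- which(set_animal == animals[ai])
    for (s in sets) {
      rows <- which(set_id == s)
      u <- outer(X[rows, 1], beta_grid)        # rows x beta grid
      p <- sweep(exp(u), 2, colSums(exp(u)), "/")
      ll[ai, ] <- ll[ai, ] + log(p[rows == used_row[s], ])
    }
  }
  lp <- matrix(-Inf, length(mu_grid), length(sigma_grid))
  for (i in seq_along(mu_grid)) {
    for (j in seq_along(sigma_grid)) {
      dens <- stats::dnorm(beta_grid, mu_grid[i], sigma_grid[j])
      li <- 0
      for (ai in seq_along(animals)) {
        li <- li + log(sum(exp(ll[ai, ]) * dens) * db)
      }
      lp[i, j] <- li +
        stats::dnorm(mu_grid[i], prior$mu_mean, sqrt(prior$mu_var), log = TRUE) +
        stats::dt(sigma_grid[j] / prior$sigma_scale, prior$sigma_df, log = TRUE)
    }
  }
  w <- exp(lp - max(lp))
  sum(mu_grid * rowSums(w)) / sum(w)
}

# Effective sample size from lag-1 autocorrelation (conservative enough for
# Monte-Carlo standard errors in the contract tests).
ess_ar1 <- function(x) {
  n <- length(x)
  rho <- stats::cor(x[-1], x[-n])
  max(4, n * (1 - rho) / (1 + rho))
}

mcse_mean <- function(x) stats::sd(x) / sqrt(ess_ar1(x))
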