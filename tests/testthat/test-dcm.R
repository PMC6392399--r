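test_that("log-likelihood matches direct-enumeration oracle and closed forms", {
  cs <- toy_choice_sets(sizes = c(4, 3, 4, 2, 4), K = 2, n_animals = 2)
  dat <- prep_dcm_data(cs, c("v1", "v2"))
  # beta = 0: uniform choice over each set
  expect_equal(loglik_mixed(dat, c(0, 0)), -sum(log(dat$n_alt)),
               tolerance = 1e-12)
  # random per-animal coefficients vs enumeration
  set.seed(1)
  for (i in 1:5) {
    B <- matrix(rnorm(4, 0, 1.5), 2, 2)
    expect_equal(loglik_mixed(dat, B),
                 oracle_loglik(dat$X, dat$set_id, dat$used_row,
                               dat$set_animal, B),
                 tolerance = 1e-10)
  }
  # single-alternative sets carry no information
  cs1 <- toy_choice_sets(sizes = rep(1, 6), K = 2)
  dat1 <- prep_dcm_data(cs1, c("v1", "v2"))
  expect_equal(loglik_mixed(dat1, c(2, -3)), 0)
})

test_that("likelihood is stable for extreme utilities", {
  cs <- toy_choice_sets(sizes = c(3, 3), K = 1)
  dat <- prep_dcm_data(cs, "v1")
  ll <- loglik_mixed(dat, 500)  # |x'b| up to several hundred
  expect_true(is.finite(ll))
})

test_that("choice probabilities sum to one and are location invariant", {
  cs <- toy_choice_sets(sizes = c(5, 3, 4), K = 2, n_animals = 3)
  dat <- prep_dcm_data(cs, c("v1", "v2"))
  B <- matrix(c(1.2, -0.4, 0.3, 2, -1, 0.5), 3, 2)
  p <- choice_probabilities(dat, B)
  expect_equal(as.numeric(tapply(p, dat$set_id, sum)), rep(1, 3),
               tolerance = 1e-12)
  # shift every alternative of each set by a constant per variable
  dat2 <- dat
  for (s in unique(dat2$set_id)) {
    dat2$X[dat2$set_id == s, ] <-
      sweep(dat2$X[dat2$set_id == s, , drop = FALSE], 2, c(5, -7), "+")
  }
  expect_equal(choice_probabilities(dat2, B), p, tolerance = 1e-12)
  expect_equal(loglik_mixed(dat2, B), loglik_mixed(dat, B), tolerance = 1e-10)
})

test_that("R-hat matches the textbook formula and flags divergence", {
  set.seed(6)
  draws <- matrix(rnorm(3 * 400), 400, 3)
  expect_equal(gelman_rubin(draws), oracle_rhat(draws), tolerance = 1e-10)
  # heavier, autocorrelated chains
  ar <- replicate(3, as.numeric(arima.sim(list(ar = 0.6), 300)))
  expect_equal(gelman_rubin(ar), oracle_rhat(ar), tolerance = 1e-10)
  # same-distribution chains converge to 1
  big <- matrix(rnorm(2 * 5000), 5000, 2)
  expect_lt(gelman_rubin(big), 1.05)
  # separated chains blow up
  off <- cbind(rnorm(200), rnorm(200) + 10)
  expect_gt(gelman_rubin(off), 1.1)
  expect_error(gelman_rubin(cbind(rep(1, 50), rep(1, 50))), "degenerate")
  expect_error(gelman_rubin(matrix(rnorm(50), 50, 1)), "2 chains")
})

test_that("null-model DIC takes its closed form", {
  cs <- toy_choice_sets(sizes = c(4, 6, 3, 5, 2), K = 2)
  fit0 <- fit_mixed_logit(cs, character(0), model_name = "random")
  d <- dic(fit0)
  expect_equal(d$DIC, 2 * sum(log(c(4, 6, 3, 5, 2))), tolerance = 1e-12)
  expect_equal(d$pD, 0)
})

test_that("Dbar equals oracle re-averaging of per-draw deviances", {
  set.seed(19)
  beta_true <- matrix(rnorm(4, 0, 0.8), 2, 2)
  cs <- toy_choice_sets(sizes = rep(5, 30), K = 2, n_animals = 2,
                        beta = beta_true)
  fit <- fit_mixed_logit(cs, c("v1", "v2"),
                         mcmc = mcmc_config(n_iter = 600, n_burnin = 300,
                                            thin = 3, seed = 5,
                                            max_rounds = 1))
  d <- dic(fit)
  devs <- c()
  for (ch in fit$draws) {
    for (t in seq_len(nrow(ch$mu))) {
      devs <- c(devs, -2 * oracle_loglik(fit$data$X, fit$data$set_id,
                                         fit$data$used_row,
                                         fit$data$set_animal,
                                         ch$beta[t, , , drop = TRUE]))
    }
  }
  expect_equal(d$Dbar, mean(devs), tolerance = 1e-8)
  expect_true(d$pD > 0)
})

test_that("model ranking computes deltas, flags, and rejects mixed data", {
  mk_null <- function(log_sum, fp) {
    structure(list(model_name = "m", null_model = TRUE,
                   data = list(log_setsize_sum = log_sum, fingerprint = fp)),
              class = "dcm_fit")
  }
  fp <- c(S = 10, n = 40, sizes = 160, used = 100, animals = 2)
  fits <- list(a = mk_null(50, fp), b = mk_null(51.5, fp), c = mk_null(60, fp))
  r <- rank_models(fits)
  expect_equal(r$model, c("a", "b", "c"))
  expect_equal(r$delta_DIC, c(0, 3, 20))
  expect_equal(r$competitive, c(TRUE, TRUE, FALSE))
  # identical models tie at delta 0
  r2 <- rank_models(list(x = mk_null(50, fp), y = mk_null(50, fp)))
  expect_equal(r2$delta_DIC, c(0, 0))
  fp2 <- fp; fp2["n"] <- 41
  expect_error(rank_models(list(a = mk_null(50, fp), b = mk_null(50, fp2))),
               "different choice sets")
})

test_that("posterior summaries match a sorting oracle and the CrI rule", {
  set.seed(23)
  beta_true <- matrix(c(1.6, 1.4, -0.1, 0.1), 2, 2)
  cs <- toy_choice_sets(sizes = rep(6, 60), K = 2, n_animals = 2,
                        beta = beta_true)
  fit <- fit_mixed_logit(cs, c("v1", "v2"),
                         mcmc = mcmc_config(n_iter = 800, n_burnin = 400,
                                            seed = 9, max_rounds = 1))
  sm <- posterior_summary(fit)
  for (k in 1:2) {
    pooled <- sort(unlist(lapply(fit$draws, function(ch) ch$mu[, k])))
    n <- length(pooled)
    h <- (n - 1) * 0.025 + 1
    lo <- pooled[floor(h)] + (h - floor(h)) *
      (pooled[ceiling(h)] - pooled[floor(h)])
    h2 <- (n - 1) * 0.975 + 1
    hi <- pooled[floor(h2)] + (h2 - floor(h2)) *
      (pooled[ceiling(h2)] - pooled[floor(h2)])
    expect_equal(sm$lower[k], lo, tolerance = 1e-12)
    expect_equal(sm$upper[k], hi, tolerance = 1e-12)
    expect_true(sm$lower[k] <= sm$mean[k] & sm$mean[k] <= sm$upper[k])
    expect_equal(sm$important[k], sm$lower[k] > 0 | sm$upper[k] < 0)
  }
})

test_that("zero-information data return the prior on the population mean", {
  # identical covariates within each set: the likelihood is flat
  set.seed(33)
  rows <- lapply(1:40, function(s) {
    v <- rnorm(1)
    data.frame(choice_set_id = s, animal_id = paste0("A", 1 + s %% 3),
               unit_id = as.character(1:4), used = c(1, 0, 0, 0), v1 = v)
  })
  cs <- do.call(rbind, rows)
  dat <- prep_dcm_data(cs, "v1")
  fit <- fit_mixed_logit(dat, "v1",
                         mcmc = mcmc_config(n_iter = 6000, n_burnin = 2000,
                                            thin = 2, seed = 3,
                                            max_rounds = 1))
  mu <- unlist(lapply(fit$draws, function(ch) ch$mu[, 1]))
  se <- mcse_mean(mu)
  expect_lt(abs(mean(mu) - 0), 4 * se)
  # prior variance 2.786; allow generous MC slack on the second moment
  expect_lt(abs(var(mu) - 2.786) / 2.786, 0.2)
})

test_that("pooled posterior mean tracks the fixed-effect MLE when sigma* = 0", {
  set.seed(41)
  b <- c(0.9, -0.6)
  beta_true <- matrix(b, 8, 2, byrow = TRUE)  # no individual heterogeneity
  cs <- toy_choice_sets(sizes = rep(8, 240), K = 2, n_animals = 8,
                        beta = beta_true)
  dat <- prep_dcm_data(cs, c("v1", "v2"))
  mle <- optim(c(0, 0), function(th)
    -oracle_loglik(dat$X, dat$set_id, dat$used_row, dat$set_animal,
                   matrix(th, 8, 2, byrow = TRUE)),
    method = "BFGS")$par
  fit <- fit_mixed_logit(dat, c("v1", "v2"),
                         mcmc = mcmc_config(n_iter = 1500, n_burnin = 700,
                                            seed = 11, max_rounds = 1))
  sm <- posterior_summary(fit)
  post_sd <- vapply(1:2, function(k)
    sd(unlist(lapply(fit$draws, function(ch) ch$mu[, k]))), numeric(1))
  expect_lt(abs(sm$mean[1] - mle[1]), 2.5 * post_sd[1])
  expect_lt(abs(sm$mean[2] - mle[2]), 2.5 * post_sd[2])
})
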