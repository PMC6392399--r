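#' Prior hyperparameters for the mixed logit hierarchy
#'
#' Population means get `mu_k ~ Normal(mu_mean, mu_var)` (variance
#' parameterization; the default 2.786 is a weakly informative logit-scale
#' prior) and population SDs a half-t, `sigma_k ~ t(0, sigma_scale,
#' sigma_df)` truncated to positive values (default scale 2, 3 df).
#'
#' @param mu_mean,mu_var Normal prior mean and variance for `mu_k`.
#' @param sigma_scale,sigma_df Half-t scale and degrees of freedom for
#'   `sigma_k`.
#' @return A list of class `prior_config`.
#' @export
prior_config <- function(mu_mean = 0, mu_var = 2.786,
                         sigma_scale = 2, sigma_df = 3) {
  stopifnot(mu_var > 0, sigma_scale > 0, sigma_df > 0)
  structure(list(mu_mean = mu_mean, mu_var = mu_var,
                 sigma_scale = sigma_scale, sigma_df = sigma_df),
            class = "prior_config")
}

#' MCMC settings
#'
#' @param chains Number of chains (>= 2, so that R-hat is defined).
#' @param n_iter Iterations per chain including burn-in.
#' @param n_burnin Burn-in (adaptation) iterations.
#' @param thin Thinning interval for stored draws.
#' @param seed Master seed; per-chain seeds are derived deterministically.
#' @param max_rounds Maximum run-length doublings: when any monitored R-hat
#'   is >= 1.1 after a round, the run is repeated with doubled length, up to
#'   this many rounds.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 3, n_iter = 3000, n_burnin = 1000,
                        thin = 2, seed = 1, max_rounds = 2) {
  stopifnot(chains >= 2, n_iter > n_burnin, thin >= 1, max_rounds >= 1)
  structure(list(chains = chains, n_iter = n_iter, n_burnin = n_burnin,
                 thin = thin, seed = seed, max_rounds = max_rounds),
            class = "mcmc_config")
}

#' Prepare choice-set data for model fitting
#'
#' Extracts the design for one candidate model from a long choice-set table:
#' renumbers sets contiguously, indexes choosers, standardizes the selected
#' covariate columns by two standard deviations over all design rows (the
#' stratum convention), and drops zero-variance covariates.
#'
#' @param cs A `choice_sets` long data frame.
#' @param variables Covariate column names for this model (may be empty for
#'   the random/null model).
#' @param std_params Optional standardization parameters to reuse (see
#'   [standardize_2sd()]).
#' @return A list of class `dcm_data`: `X` (standardized design), `set_id`,
#'   `used_row`, `set_animal`, `animal_ids`, `variables`, `std`,
#'   `log_setsize_sum`, `fingerprint`.
#' @export
prep_dcm_data <- function(cs, variables, std_params = NULL) {
  stopifnot(all(variables %in% names(cs)))
  ord <- order(cs$choice_set_id)
  cs <- cs[ord, , drop = FALSE]
  set_id <- match(cs$choice_set_id, unique(cs$choice_set_id))
  S <- max(set_id, 0L)
  used_row <- which(cs$used == 1L)
  if (length(used_row) != S) stop("each choice set needs exactly one used row")
  first_row <- match(seq_len(S), set_id)
  animal_ids <- unique(cs$animal_id[first_row])
  set_animal <- match(cs$animal_id[first_row], animal_ids)
  n_alt <- tabulate(set_id, nbins = S)
  if (length(variables)) {
    std <- standardize_2sd(as.matrix(cs[, variables, drop = FALSE]),
                           params = std_params)
    X <- std$X_std
  } else {
    std <- list(params = NULL, excluded = character(0))
    X <- matrix(0, nrow(cs), 0)
  }
  structure(list(
    X = X, set_id = set_id, used_row = used_row, set_animal = set_animal,
    animal_ids = animal_ids, variables = colnames(X), std = std,
    n_alt = n_alt, log_setsize_sum = sum(log(n_alt)),
    fingerprint = c(S = S, n = nrow(cs), sizes = sum(n_alt^2),
                    used = sum(used_row), animals = length(animal_ids))
  ), class = "dcm_data")
}

#' Mixed conditional-logit log-likelihood
#'
#' Sum over choice sets of `x_used' b_i - log sum_j exp(x_j' b_i)` with
#' `b_i` the chooser's coefficient vector, evaluated with a max-shifted
#' log-sum-exp (stable for utilities up to |x'b| ~ 700).
#'
#' @param dat A `dcm_data` object from [prep_dcm_data()].
#' @param beta Either a length-K vector (shared coefficients) or an
#'   animals-by-K matrix of individual coefficients.
#' @return Scalar log-likelihood (0 when every set has one alternative or
#'   the model has no covariates and sets are singletons).
#' @export
loglik_mixed <- function(dat, beta) {
  I <- length(dat$animal_ids)
  K <- ncol(dat$X)
  if (K == 0) return(-dat$log_setsize_sum)
  B <- if (is.matrix(beta)) beta else
    matrix(beta, I, K, byrow = TRUE)
  stopifnot(nrow(B) == I, ncol(B) == K)
  sum(cl_loglik_by_animal(dat$X, dat$set_id, dat$used_row, dat$set_animal,
                          B, I))
}

#' Choice probabilities within each set
#'
#' Plain softmax of utilities per choice set; mostly useful for checks of
#' the likelihood's invariances (probabilities sum to one per set, and are
#' unchanged by adding a constant to all alternatives of a set).
#'
#' @inheritParams loglik_mixed
#' @return Numeric vector, one probability per design row.
#' @export
choice_probabilities <- function(dat, beta) {
  I <- length(dat$animal_ids)
  K <- ncol(dat$X)
  if (K == 0) return(1 / dat$n_alt[dat$set_id])
  B <- if (is.matrix(beta)) beta else matrix(beta, I, K, byrow = TRUE)
  u <- rowSums(dat$X * B[dat$set_animal[dat$set_id], , drop = FALSE])
  mx <- stats::ave(u, dat$set_id, FUN = max)
  eu <- exp(u - mx)
  eu / stats::ave(eu, dat$set_id, FUN = sum)
}

#' @keywords internal
log_half_t <- function(sigma, scale, df) {
  # truncated-t log density up to a constant, on sigma > 0
  stats::dt(sigma / scale, df, log = TRUE) - log(scale)
}

#' @keywords internal
run_chain <- function(dat, prior, n_iter, n_burnin, thin, seed) {
  set.seed(seed)
  I <- length(dat$animal_ids); K <- ncol(dat$X)
  mu <- stats::rnorm(K, 0, 1)
  sigma <- stats::runif(K, 0.3, 1.5)
  B <- matrix(stats::rnorm(I * K, rep(mu, each = I), 0.25), I, K)
  scale_i <- rep(0.4, I)
  sig_step <- rep(0.4, K)
  ll <- cl_loglik_by_animal(dat$X, dat$set_id, dat$used_row, dat$set_animal,
                            B, I)
  n_keep <- (n_iter - n_burnin) %/% thin
  mu_d <- matrix(NA_real_, n_keep, K)
  sig_d <- matrix(NA_real_, n_keep, K)
  beta_d <- array(NA_real_, c(n_keep, I, K))
  dev_d <- numeric(n_keep)
  kept <- 0L
  for (t in seq_len(n_iter)) {
    ## individual coefficients: joint random-walk per animal, accepted
    ## independently (the b_i are conditionally independent)
    Bp <- B + matrix(stats::rnorm(I * K), I, K) * scale_i
    llp <- cl_loglik_by_animal(dat$X, dat$set_id, dat$used_row,
                               dat$set_animal, Bp, I)
    Mu <- matrix(mu, I, K, byrow = TRUE)
    Sg <- matrix(sigma, I, K, byrow = TRUE)
    la <- (llp - ll) +
      rowSums(stats::dnorm(Bp, Mu, Sg, log = TRUE)) -
      rowSums(stats::dnorm(B, Mu, Sg, log = TRUE))
    acc <- log(stats::runif(I)) < la
    if (any(acc)) {
      B[acc, ] <- Bp[acc, ]
      ll[acc] <- llp[acc]
    }
    ## population means: conjugate normal draw
    prec <- 1 / prior$mu_var + I / sigma^2
    mn <- (colSums(B) / sigma^2 + prior$mu_mean / prior$mu_var) / prec
    mu <- stats::rnorm(K, mn, sqrt(1 / prec))
    ## population SDs: random walk on log sigma with half-t prior
    for (k in seq_len(K)) {
      lsp <- log(sigma[k]) + stats::rnorm(1, 0, sig_step[k])
      sp <- exp(lsp)
      la_s <- sum(stats::dnorm(B[, k], mu[k], sp, log = TRUE)) -
        sum(stats::dnorm(B[, k], mu[k], sigma[k], log = TRUE)) +
        log_half_t(sp, prior$sigma_scale, prior$sigma_df) -
        log_half_t(sigma[k], prior$sigma_scale, prior$sigma_df) +
        lsp - log(sigma[k])  # jacobian of the log transform
      acc_s <- log(stats::runif(1)) < la_s
      if (acc_s) sigma[k] <- sp
      if (t <= n_burnin) {
        sig_step[k] <- exp(log(sig_step[k]) +
                             (as.numeric(acc_s) - 0.35) / sqrt(t))
      }
    }
    if (t <= n_burnin) {
      scale_i <- exp(log(scale_i) + (as.numeric(acc) - 0.25) / sqrt(t))
      scale_i <- pmin(pmax(scale_i, 1e-3), 10)
    } else if ((t - n_burnin) %% thin == 0) {
      kept <- kept + 1L
      mu_d[kept, ] <- mu
      sig_d[kept, ] <- sigma
      beta_d[kept, , ] <- B
      dev_d[kept] <- -2 * sum(ll)
    }
  }
  list(mu = mu_d, sigma = sig_d, beta = beta_d, deviance = dev_d)
}

#' Fit the Bayesian mixed conditional logit by MCMC
#'
#' Adaptive random-walk Metropolis within Gibbs over the hierarchy
#' `b_ik ~ Normal(mu_k, sigma_k^2)`, `mu_k ~ Normal(0, 2.786)`,
#' `sigma_k ~ half-t(2, 3)`: animal coefficient blocks and log-sigma move by
#' adaptive random walks (targeting roughly 25-35% acceptance during
#' burn-in), the population means by their conjugate normal conditional.
#' Multiple chains start from overdispersed points; if any monitored R-hat
#' (mu and sigma) is >= 1.1, the run length is doubled and the model refit,
#' up to `mcmc$max_rounds` rounds.  With an empty variable set the fit is
#' the closed-form null (random-choice) model and no sampling is done.
#'
#' @param cs A `choice_sets` data frame, or a prepared `dcm_data` object.
#' @param variables Covariate columns defining the candidate model.
#' @param prior A [prior_config()].
#' @param mcmc An [mcmc_config()].
#' @param std_params Optional standardization parameters to reuse.
#' @param model_name Label carried into summaries.
#' @return An object of class `dcm_fit` with elements `draws` (per chain),
#'   `rhat`, `converged`, `data`, `model_name`, and for the null model the
#'   constant deviance.
#' @export
fit_mixed_logit <- function(cs, variables, prior = prior_config(),
                            mcmc = mcmc_config(), std_params = NULL,
                            model_name = "model") {
  dat <- if (inherits(cs, "dcm_data")) cs else
    prep_dcm_data(cs, variables, std_params = std_params)
  K <- ncol(dat$X)
  if (K == 0) {
    fit <- structure(list(
      model_name = model_name, data = dat, prior = prior, mcmc = mcmc,
      draws = NULL, rhat = numeric(0), converged = TRUE, null_model = TRUE),
      class = "dcm_fit")
    return(fit)
  }
  if (length(dat$animal_ids) < 1) stop("need at least one animal")
  n_iter <- mcmc$n_iter; n_burnin <- mcmc$n_burnin
  for (round in seq_len(mcmc$max_rounds)) {
    chains <- lapply(seq_len(mcmc$chains), function(ch) {
      run_chain(dat, prior, n_iter, n_burnin, mcmc$thin,
                seed = (mcmc$seed * 1000L + round * 100L + ch) %% .Machine$integer.max)
    })
    rhat <- monitor_rhat(chains)
    if (all(rhat < 1.1)) break
    n_iter <- n_iter * 2L; n_burnin <- n_burnin * 2L
  }
  structure(list(
    model_name = model_name, data = dat, prior = prior, mcmc = mcmc,
    n_iter_used = n_iter, draws = chains, rhat = rhat,
    converged = all(rhat < 1.1), null_model = FALSE),
    class = "dcm_fit")
}

#' @keywords internal
monitor_rhat <- function(chains) {
  K <- ncol(chains[[1]]$mu)
  out <- numeric(0)
  for (k in seq_len(K)) {
    out[paste0("mu_", k)] <-
      gelman_rubin(sapply(chains, function(ch) ch$mu[, k]))
    out[paste0("sigma_", k)] <-
      gelman_rubin(sapply(chains, function(ch) ch$sigma[, k]))
  }
  out
}

#' @export
print.dcm_fit <- function(x, ...) {
  if (isTRUE(x$null_model)) {
    cat(sprintf("<dcm_fit> %s: null (random-choice) model, %d sets\n",
                x$model_name, length(x$data$n_alt)))
  } else {
    cat(sprintf(
      "<dcm_fit> %s: %d variables, %d animals, %d sets; %d chains x %d kept; %s\n",
      x$model_name, ncol(x$data$X), length(x$data$animal_ids),
      length(x$data$n_alt), length(x$draws), nrow(x$draws[[1]]$mu),
      if (x$converged) "converged (all R-hat < 1.1)"
      else sprintf("NOT converged (max R-hat %.3f)", max(x$rhat))))
  }
  invisible(x)
}

#' Brooks-Gelman-Rubin potential scale reduction factor
#'
#' The classic split-free PSRF for one scalar parameter:
#' `sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean within-chain variance
#' and `B` the between-chain variance of chain means times n.  Values below
#' 1.1 are taken as convergence.
#'
#' @param draws Matrix with one column per chain (equal lengths >= 10).
#' @return The R-hat value.
#' @export
gelman_rubin <- function(draws) {
  draws <- as.matrix(draws)
  m <- ncol(draws); n <- nrow(draws)
  if (m < 2) stop("R-hat needs at least 2 chains")
  if (n < 10) stop("chains too short for R-hat")
  W <- mean(apply(draws, 2, stats::var))
  if (W == 0) stop("degenerate chains: zero within-chain variance")
  B <- n * stats::var(colMeans(draws))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Deviance information criterion of a fitted model
#'
#' `Dbar` is the posterior mean of the deviance `-2 log L` evaluated with
#' the individual-level coefficients at each draw; the effective number of
#' parameters is `pD = Dbar - D(posterior mean of the b_i)`; and
#' `DIC = Dbar + pD`.  For the null model the deviance is the constant
#' `2 * sum(log |C_n|)` and `pD = 0`.
#'
#' @param fit A `dcm_fit`.
#' @return List with `Dbar`, `pD`, `DIC`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "dcm_fit"))
  if (isTRUE(fit$null_model)) {
    D0 <- 2 * fit$data$log_setsize_sum
    return(list(Dbar = D0, pD = 0, DIC = D0))
  }
  if (is.null(fit$draws) || !length(fit$draws)) stop("fit has no draws")
  dev <- unlist(lapply(fit$draws, `[[`, "deviance"))
  Dbar <- mean(dev)
  Bbar <- Reduce(`+`, lapply(fit$draws, function(ch) {
    apply(ch$beta, c(2, 3), mean)
  })) / length(fit$draws)
  Dhat <- -2 * loglik_mixed(fit$data, Bbar)
  pD <- Dbar - Dhat
  list(Dbar = Dbar, pD = pD, DIC = Dbar + pD)
}

#' Rank candidate models by DIC
#'
#' Computes `delta_DIC = DIC - min(DIC)` across candidate fits of the same
#' choice sets; models within 5 DIC units of the best are flagged
#' competitive.  Fits on different data are rejected.
#'
#' @param fits Named list of `dcm_fit` objects.
#' @param competitive_delta Competitiveness threshold (default 5).
#' @return Data frame sorted by DIC: model, Dbar, pD, DIC, delta_DIC,
#'   competitive.
#' @export
rank_models <- function(fits, competitive_delta = 5) {
  stopifnot(length(fits) >= 2)
  fps <- lapply(fits, function(f) f$data$fingerprint)
  if (!all(vapply(fps, identical, logical(1), fps[[1]]))) {
    stop("models were fitted on different choice sets")
  }
  d <- lapply(fits, dic)
  out <- data.frame(
    model = if (!is.null(names(fits))) names(fits)
            else vapply(fits, `[[`, character(1), "model_name"),
    Dbar = vapply(d, `[[`, numeric(1), "Dbar"),
    pD = vapply(d, `[[`, numeric(1), "pD"),
    DIC = vapply(d, `[[`, numeric(1), "DIC"),
    row.names = NULL)
  out$delta_DIC <- out$DIC - min(out$DIC)
  out$competitive <- out$delta_DIC <= competitive_delta
  out[order(out$DIC), , drop = FALSE]
}

#' Posterior summary of population-level selection coefficients
#'
#' Per variable: the posterior mean of the population mean `mu_k`, its
#' percentile 95% credible interval from the pooled draws, the posterior
#' mean of `sigma_k`, the R-hat of `mu_k`, and the importance call (the
#' credible interval excludes zero).  The returned table is the input to
#' caterpillar plots.
#'
#' @param fit A `dcm_fit`.
#' @param prob Credible-interval mass (default 0.95).
#' @return Data frame, one row per variable, of class `posterior_summary`.
#' @export
posterior_summary <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "dcm_fit"))
  if (isTRUE(fit$null_model)) {
    return(structure(data.frame(variable = character(0)),
                     class = c("posterior_summary", "data.frame")))
  }
  K <- ncol(fit$data$X)
  a <- (1 - prob) / 2
  rows <- lapply(seq_len(K), function(k) {
    mu_k <- unlist(lapply(fit$draws, function(ch) ch$mu[, k]))
    sg_k <- unlist(lapply(fit$draws, function(ch) ch$sigma[, k]))
    q <- unname(stats::quantile(mu_k, c(a, 1 - a), type = 7))
    data.frame(variable = fit$data$variables[k],
               mean = mean(mu_k), lower = q[1], upper = q[2],
               sigma_mean = mean(sg_k),
               rhat = fit$rhat[paste0("mu_", k)],
               important = q[1] > 0 | q[2] < 0,
               row.names = NULL)
  })
  structure(do.call(rbind, rows),
            class = c("posterior_summary", "data.frame"))
}

#' @export
summary.dcm_fit <- function(object, ...) posterior_summary(object, ...)
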