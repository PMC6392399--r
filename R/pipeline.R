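#' Run configuration for the full analysis
#'
#' Bundles every threshold and setting of the pipeline: step-scale cutoffs,
#' the feed-refuge buffer, choice-grid spacing, the availability quantile,
#' the correlation-screen threshold, the DIC competitiveness margin, the
#' convergence cutoff, season windows, priors and MCMC settings.  Unknown
#' arguments are rejected before any computation.
#'
#' @param ... Overrides of the defaults listed below.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    censor_days = 4,
    fine_km = 0.33,
    local_max_km = 25,
    buffer_m = 400,
    spacing_km = 2.12,
    availability_q = 0.975,
    radius_km = NULL,          # NULL: derive from the local-step quantile
    cor_threshold = 0.8,
    ddic_competitive = 5,
    rhat_limit = 1.1,
    lat = 42.47, lon = -82.66,
    season_windows = default_season_windows(),
    seasons = c("PRE", "FIRST", "SECOND", "POST"),
    prior = prior_config(),
    mcmc = mcmc_config(),
    seed = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown run_config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  num <- c("fine_km", "local_max_km", "buffer_m", "spacing_km",
           "availability_q", "cor_threshold", "ddic_competitive", "rhat_limit")
  bad <- num[vapply(num, function(k) cfg[[k]] <= 0, logical(1))]
  if (length(bad)) stop("thresholds must be positive: ", paste(bad, collapse = ", "))
  if (cfg$censor_days < 0) stop("censor_days must be non-negative")
  structure(cfg, class = "run_config")
}

#' @keywords internal
write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Run the full resource-selection analysis
#'
#' End-to-end pipeline: censor the post-release window; label diel period
#' and season; classify step scales and keep local-scale fixes; derive the
#' availability radius from the local step lengths (unless fixed in the
#' config); build per-stratum choice sets; screen correlated covariates;
#' fit the four candidate models (random, resource, risk, full) per
#' season-by-diel stratum; rank them by DIC; and summarize the top model's
#' posterior.  Artifacts (filter ledger, descriptive table, screening log,
#' DIC table, posterior summaries / caterpillar data, run manifest) are
#' written to `out_dir` when given.
#'
#' @param fixes Fix data frame (see [read_fixes()]).
#' @param landscape A `landscape_grid`.
#' @param config A [run_config()].
#' @param out_dir Optional output directory for artifacts.
#' @return A list: `ledger`, `table2`, `radius`, `strata` (per-stratum
#'   screening, DIC ranking, summaries), `manifest`.
#' @export
run_analysis <- function(fixes, landscape, config = run_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  catalog <- landscape$catalog

  cen <- censor_initial(fixes, days = config$censor_days)
  f <- classify_diel(cen$fixes, lat = config$lat, lon = config$lon)
  f$season <- assign_season(f$timestamp, windows = config$season_windows)
  ss <- steps_and_scales(f, fine_km = config$fine_km,
                         local_max_km = config$local_max_km)
  f <- ss$fixes
  local_lengths <- ss$steps$length_km[ss$steps$scale == "local"]
  radius <- if (is.null(config$radius_km)) {
    availability_radius(local_lengths, q = config$availability_q)
  } else config$radius_km

  cgrid <- choice_grid(origin = landscape$origin,
                       spacing_km = config$spacing_km)
  units <- resource_units(cgrid, landscape)
  cs_all <- build_choice_sets(f, cgrid, units = units, radius_km = radius)
  n_out <- attr(cs_all, "n_out_of_extent")
  ledger <- filter_ledger(total = ss$ledger$total, fine = ss$ledger$fine,
                          relocation = ss$ledger$relocation,
                          out_of_extent = n_out,
                          censored_initial = cen$n_censored)
  cs_all <- aggregate_covariates(cs_all, catalog)
  # descriptive table covers the fixes that produced a choice set
  table2 <- descriptive_table(
    cs_all[cs_all$used == 1L, c("animal_id", "season", "diel")],
    seasons = config$seasons)

  strata <- list()
  for (s in config$seasons) for (dl in c("diurnal", "nocturnal")) {
    cs <- cs_all[!is.na(cs_all$season) & cs_all$season == s &
                   cs_all$diel == dl, , drop = FALSE]
    if (!nrow(cs)) next
    vars <- intersect(catalog$abbrev, names(cs))
    scr <- screen_correlation(cs[, vars, drop = FALSE],
                              threshold = config$cor_threshold)
    cand <- candidate_models(catalog, retained = scr$retained)
    fits <- list()
    for (m in names(cand)) {
      fits[[m]] <- fit_mixed_logit(cs, cand[[m]], prior = config$prior,
                                   mcmc = config$mcmc, model_name = m)
    }
    ranking <- rank_models(fits, competitive_delta = config$ddic_competitive)
    top <- ranking$model[1]
    strata[[paste(s, dl, sep = "_")]] <- list(
      season = s, diel = dl, n_sets = length(unique(cs$choice_set_id)),
      screening = scr, ranking = ranking,
      summary = posterior_summary(fits[[top]]),
      converged = vapply(fits, `[[`, logical(1), "converged"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("duckchoice")),
    seed = config$seed,
    radius_km = as.numeric(radius),
    radius_reported = if (!is.null(attr(radius, "reported")))
      attr(radius, "reported") else round(as.numeric(radius), 1),
    config_hash = config_hash(config),
    n_strata = length(strata))
  res <- list(ledger = ledger, table2 = table2, radius = radius,
              strata = strata, manifest = manifest)
  if (!is.null(out_dir)) write_artifacts(res, out_dir)
  invisible(res)
}

#' @keywords internal
config_hash <- function(config) {
  plain <- rapply(unclass(config), function(x)
    if (inherits(x, "Date")) format(x) else x, how = "replace")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, force = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

#' @keywords internal
write_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_json_artifact(unclass(res$ledger), file.path(out_dir, "ledger.json"))
  utils::write.csv(res$table2, file.path(out_dir, "descriptive_table.csv"),
                   row.names = FALSE)
  rank_rows <- list(); sum_rows <- list(); scr_rows <- list()
  for (nm in names(res$strata)) {
    st <- res$strata[[nm]]
    r <- st$ranking; r$season <- st$season; r$diel <- st$diel
    rank_rows[[nm]] <- r
    if (nrow(st$summary)) {
      sm <- st$summary; sm$season <- st$season; sm$diel <- st$diel
      sum_rows[[nm]] <- sm
    }
    if (nrow(st$screening$log)) {
      lg <- st$screening$log; lg$season <- st$season; lg$diel <- st$diel
      scr_rows[[nm]] <- lg
    }
  }
  utils::write.csv(do.call(rbind, rank_rows),
                   file.path(out_dir, "dic_table.csv"), row.names = FALSE)
  if (length(sum_rows)) {
    utils::write.csv(do.call(rbind, sum_rows),
                     file.path(out_dir, "caterpillar.csv"), row.names = FALSE)
  }
  if (length(scr_rows)) {
    utils::write.csv(do.call(rbind, scr_rows),
                     file.path(out_dir, "screening_log.csv"), row.names = FALSE)
  }
  write_json_artifact(res$manifest, file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' Parameter-recovery simulation study
#'
#' Repeatedly simulates telemetry from known population coefficients, runs
#' the pipeline (step filtering, destination-anchored choice sets, 2-SD
#' standardization reusing the simulator's unit-level parameters), fits the
#' full (true-variable) model and the null model, and reports per-replicate
#' estimates, credible intervals, coverage of the truth, and the
#' full-versus-null DIC margin.
#'
#' @param cfg A [sim_config()]; the default study design uses 40 animals
#'   with about 150 modelled choices each and an availability radius that
#'   covers the whole layer, so the destination-anchored analysis sets
#'   coincide with the generating sets and the fitted likelihood is exact
#'   (see the methods vignette for why a radius-truncated destination
#'   anchor is not a valid generative inverse).
#' @param n_replicates Number of replicate datasets.
#' @param analysis_radius_km Availability radius used by the analysis
#'   (default covers the diagonal of the default recovery landscape).
#' @param mcmc MCMC settings per fit.
#' @param out_dir Optional artifact directory (CSV + JSON report).
#' @return Data frame with one row per replicate and variable: estimate,
#'   CrI, truth, covered, bias, and the replicate's `delta_DIC` of the null
#'   model relative to the full model.
#' @export
run_simulation_study <- function(cfg = NULL, n_replicates = 5,
                                 analysis_radius_km = 10,
                                 mcmc = mcmc_config(n_iter = 1200,
                                                    n_burnin = 500),
                                 out_dir = NULL) {
  if (is.null(cfg)) cfg <- recovery_sim_config()
  ls <- generate_landscape(cfg)
  rows <- list()
  for (rep in seq_len(n_replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + 1000L * rep
    sim <- simulate_trajectories(cfg_r, ls)
    fit <- recovery_fit(sim, cfg_r, analysis_radius_km,
                        mcmc_config(chains = mcmc$chains, n_iter = mcmc$n_iter,
                                    n_burnin = mcmc$n_burnin, thin = mcmc$thin,
                                    seed = mcmc$seed + rep,
                                    max_rounds = mcmc$max_rounds))
    sm <- fit$summary
    for (k in seq_len(nrow(sm))) {
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = rep, variable = sm$variable[k],
        truth = unname(sim$truth$mu_star[sm$variable[k]]),
        estimate = sm$mean[k], lower = sm$lower[k], upper = sm$upper[k],
        covered = sm$lower[k] <= sim$truth$mu_star[sm$variable[k]] &
          sim$truth$mu_star[sm$variable[k]] <= sm$upper[k],
        sigma_mean = sm$sigma_mean[k], rhat = sm$rhat[k],
        ddic_null = fit$ddic_null, n_sets = fit$n_sets)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$bias <- out$estimate - out$truth
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "recovery.csv"),
                     row.names = FALSE)
    agg <- recovery_report(out)
    write_json_artifact(agg, file.path(out_dir, "recovery_summary.json"))
  }
  out
}

#' Default design of the parameter-recovery study
#'
#' 40 animals, 8 fixes per day over 20 days (about 150 modelled choices per
#' animal), no fine or relocation displacements, distance-free availability
#' on a 7 km landscape (so each choice set holds roughly a dozen units),
#' true coefficients (1.0, -0.5) on the water and marsh aggregates with
#' individual SD 0.3.
#'
#' @param seed Master seed.
#' @return A [sim_config()].
#' @export
recovery_sim_config <- function(seed = 1) {
  sim_config(seed = seed, n_animals = 40, fixes_per_day = 8,
             start = "2015-10-01", end = "2015-10-19",
             extent_km = 7, patch_cells = 8, n_feed_sites = 2,
             radius_km = 5, p_fine = 0, p_reloc = 0,
             variables = c("res_water", "res_marsh"),
             mu_star = c(1.0, -0.5), sigma_star = c(0.3, 0.3),
             anchor = "global")
}

#' @keywords internal
recovery_fit <- function(sim, cfg, analysis_radius_km, mcmc) {
  ss <- steps_and_scales(sim$fixes, fine_km = cfg$fine_km,
                         local_max_km = cfg$local_max_km)
  cs <- build_choice_sets(ss$fixes, sim$cgrid, units = sim$units,
                          radius_km = analysis_radius_km)
  cs <- aggregate_covariates(cs, sim$landscape$catalog)
  dat <- prep_dcm_data(cs, names(sim$truth$mu_star),
                       std_params = sim$truth$std_params)
  fit <- fit_mixed_logit(dat, names(sim$truth$mu_star), mcmc = mcmc,
                         model_name = "full")
  null <- fit_mixed_logit(prep_dcm_data(cs, character(0)), character(0),
                          model_name = "random")
  ranking <- rank_models(list(full = fit, random = null))
  list(summary = posterior_summary(fit),
       ddic_null = ranking$delta_DIC[ranking$model == "random"],
       n_sets = length(dat$n_alt), fit = fit)
}

#' Aggregate a recovery table into coverage / bias / RMSE per variable
#'
#' @param recovery Output of [run_simulation_study()].
#' @return List per variable: coverage rate, mean bias, RMSE, and the rate
#'   of replicates where the full model beat the null by more than 5 DIC.
#' @export
recovery_report <- function(recovery) {
  out <- list()
  for (v in unique(recovery$variable)) {
    sub <- recovery[recovery$variable == v, , drop = FALSE]
    out[[v]] <- list(coverage = mean(sub$covered),
                     bias = mean(sub$bias),
                     rmse = sqrt(mean(sub$bias^2)),
                     n = nrow(sub))
  }
  out$full_beats_null_rate <-
    mean(tapply(recovery$ddic_null > 5, recovery$replicate, all))
  out
}
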