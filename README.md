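# duckchoice

Bayesian discrete-choice resource selection analysis for GPS-tracked
waterfowl on managed wetland landscapes.

Dabbling ducks wintering on heavily managed wetland complexes trade
foraging opportunity against hunting-related mortality risk: public
marshes offer food but heavy disturbance, federal refuges safety but
crowding, private clubs intermediate risk with intensively managed food
(flooded crops, supplemental feed with a 400 m no-hunting buffer).
`duckchoice` implements the full analysis chain used to quantify those
trade-offs from telemetry, for movement ecologists and waterfowl managers:

* **landscape** — reclassify a land-cover raster into resource classes
  (agriculture, water, marsh, flooded agriculture, supplemental feeding
  refuge) crossed with ownership strata carrying presumed hunting-risk
  tiers, and tally per-cell covariate areas (ha);
* **movement** — censor the post-release recovery window, label fixes by
  diel period (legal shooting time: sunrise − 30 min to sunset + 30 min)
  and hunting season, classify step lengths into fine (< 0.33 km), local
  and relocation (> 25 km) scales, and account for every removed fix in a
  conservation-checked ledger;
* **choiceset** — a 2.12 km analysis grid, a data-driven availability
  radius (the 97.5th percentile of local step lengths), used/available
  choice sets anchored on the used cell, pairwise correlation screening
  (|r| ≥ 0.8) and two-standard-deviation covariate standardization;
* **dcm** — the mixed (random-effects) conditional logit

  &nbsp;&nbsp;P(y | C, βᵢ) = exp(xᵧ'βᵢ) / Σ_{j∈C} exp(xⱼ'βᵢ),
  &nbsp;βᵢₖ ~ Normal(μₖ, σₖ²), μₖ ~ Normal(0, 2.786), σₖ ~ t⁺(0, 2, 3),

  estimated by adaptive Metropolis-within-Gibbs MCMC (compiled likelihood
  kernel), with Brooks–Gelman–Rubin convergence checks (R-hat < 1.1), DIC
  ranking of the four candidate models (random / resource / risk / full,
  competitive within 5 DIC units), and the 95%-credible-interval
  importance rule for population-level coefficients μₖ;
* **synthetic data** — a seeded generator producing a patch-mosaic
  landscape with study-like composition and GPS trajectories drawn from
  the mixed-logit model with known coefficients, so every stage is
  testable without proprietary data.

## Worked example

Simulate a study-like data set and run the full analysis:

```r
library(duckchoice)

cfg <- sim_config(seed = 42, n_animals = 12, extent_km = 25, radius_km = 9.6,
                  start = "2015-09-10", end = "2015-11-20",
                  p_fine = 0.5, p_reloc = 0.002, anchor = "previous")
sim <- simulate_trajectories(cfg)

res <- run_analysis(sim$fixes, sim$landscape,
                    config = run_config(radius_km = 9.6, seed = 42,
                                        mcmc = mcmc_config(n_iter = 600,
                                                           n_burnin = 300,
                                                           seed = 42)))
print(res$ledger)
print(res$strata[["FIRST_diurnal"]]$ranking)
```

which prints (a few minutes on one core):

```
<filter_ledger>
  censored (post-release): 336 fixes
  steps total: 5700
  - fine scale: 2899
  - relocation scale: 16
  = local scale: 2785
  - out of extent: 0
  = final: 2785
     model     Dbar       pD      DIC delta_DIC competitive
2 resource 8076.761 26.73152 8103.492   0.00000        TRUE
4     full 8073.569 73.12771 8146.696  43.20411       FALSE
3     risk 8166.254 17.02496 8183.279  79.78677       FALSE
1   random 8349.950  0.00000 8349.950 246.45819       FALSE
```

The ledger shows the step-scale filtering (5,700 measured movements, of
which 2,785 were local scale and usable), and the DIC table ranks the four
candidate hypotheses for the FIRST-half-of-season diurnal stratum — here
the `resource` model wins, correctly, because this simulation generated
choices from resource-class (water/marsh) coefficients alone.  The top
model's posterior summary (`res$strata[[...]]$summary`) gives each
variable's population mean, 95% credible interval, among-individual SD,
R-hat, and importance call; in this run water is selected
(μ ≈ 0.84, CrI [0.59, 1.10], important) and marsh avoided
(μ ≈ −0.50, CrI [−0.77, −0.24], important), matching the simulated truth
of (1, −0.5) on the 2-SD-standardized scale.

A parameter-recovery study over replicate simulated datasets:

```r
rec <- run_simulation_study(cfg = recovery_sim_config(seed = 1),
                            n_replicates = 5)
recovery_report(rec)
```

reports per-variable coverage of the true coefficients, bias, RMSE, and
how often the full model beats the null by more than 5 DIC units.

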