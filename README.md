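# mwrapop

Bayesian subnational estimation and projection of counts of **married women
of reproductive age** (MWRA, ages 15–49).

MWRA counts are the denominator behind most family-planning indicators
(contraceptive prevalence, unmet need, demand satisfied), yet many
lower-income countries have no recent subnational population register to
take them from. `mwrapop` implements a regression-forecasting approach that
assembles the three demographic drivers of female population change from
survey and census data and combines them in a Bayesian hierarchical model,
producing probabilistic MWRA counts by single age for second-level
administrative units (divisions) nested in first-level units (regions),
with medians, 95% credible intervals and annual rates of change for
2000–2030:

* **Net migration** — from census microdata recording current and previous
  division of residence: person-weighted in/out/net flows by single age and
  division, proportional re-partitioning across historical boundary
  changes, age proportions of net migration (X₁), and a hierarchical
  Gaussian time-series model (ages within divisions within regions, random
  walk over time) that smooths and extrapolates them.
* **Fertility** — age-specific fertility rates (X₂) from DHS-style
  retrospective birth histories via a person-period (tfr2-style) estimator
  with sampling weights and the all-women factor, then a hierarchical
  log-scale model (random-walk age profile, exchangeable region intercepts,
  regional random walk over time).
* **Survival** — single-age, single-year survival probabilities (X₃)
  obtained by bilinear interpolation/extrapolation of abridged life-table
  ₅pₓ values anchored at age-group and period midpoints.

The population model is, per cell (age *a*, division *d*, region *r*, year
*t*):

```
log η_adrt  ~  Normal(log η*_adrt, σ²)
log η*_adrt =  β₀ + β₁·X₁,adrt + β₂·X₂,adrt·X₃,adrt + u₁,adt + u₂,drt
```

with exchangeable zero-mean normal varying effects u₁ (age × division ×
year) and u₂ (division × year), Normal(0, 10²) priors on the coefficients
and half-normal priors on all scales. Step one fits the model to the census
years; step two predicts 2000–2030 from the driver models' posteriors,
paired draw by draw so that driver uncertainty propagates. Summaries follow
the source conventions: unit-year point estimates are sums over ages of
per-cell posterior medians, intervals are 2.5th/97.5th percentiles of
per-draw totals, and the annual rate of change is
`100·(P_t2 − P_t1)/(P_t1·(t2 − t1))`. Diagnostics include the
Gelman–Rubin R̂, effective sample size, and posterior predictive p-values;
a sensitivity harness re-fits with predictors excluded or prior scales
rescaled.

Because the underlying census and survey microdata are restricted, the
package ships a synthetic-world generator with known ground truth (census
person records, birth histories, life tables) that exercises every stage
end to end; all tests run against it.

## Worked example

```r
library(mwrapop)
library(dplyr)

cfg   <- world_config(seed = 7)          # 2 regions x 4 divisions, ages 15-49
truth <- ground_truth(cfg)
census <- generate_census(cfg, truth)

# net-migration flows: person-weighted, zero-sum over the closed system
flows <- compute_flows(census, cfg$register)
sum(flows$net_count)
#> [1] 0

# population model on the census years, with the true covariate surfaces
frame <- build_frame(census_mwra_counts(census, cfg$register),
                     truth_migration_series(truth), truth_asfr_surface(truth),
                     truth_survival_surface(truth), cfg$register)
fit <- fit_population_model(frame, mcmc_settings(n_draws = 1500, burn_in = 700))
tidy(fit)
#> # A tibble: 7 x 8
#>   term       estimate std.error conf.low conf.high  rhat   ess identified
#> 1 beta0       5.97      0.00966   5.95       5.99   1.02  175. TRUE
#> 2 beta1       1.31      0.230     0.834      1.75   1.00   NA  TRUE
#> 3 beta2       1.45      0.105     1.25       1.67   1.02   NA  TRUE
#> ...
truth$betas
#>    beta0    beta1    beta2
#> 5.991465 1.000000 1.500000
```

The 95% credible intervals cover the generating coefficients. Projecting to
2030 with the true future covariates and summarising:

```r
nd   <- truth$cells |> filter(year == 2030) |>
  select(age, division, region, year, X1, X2, X3)
proj <- project_population(fit, nd, seed = 9)
summarize_projection(proj) |> filter(level == "national")
#>   level    unit      year count_median median_of_sums cri_low cri_high
#> 1 national national  2030       64550.         65234.  60489.   70868.
sum(truth$cells$eta_star[truth$cells$year == 2030])   # ground truth
#> [1] 62914.86
```

The truth lies inside the interval. `run_pipeline()` chains all stages
(simulate → migration → fertility → survival → fit → project → summarise →
diagnose → sensitivity) from a single config and writes CSV/JSON artifacts
plus a checksummed manifest; `inst/scripts/mwra-pipeline.R` is a thin
command-line wrapper.

## Scope

The package estimates long-term internal migration only (no international
flows), models fertility for all women of reproductive age, and does not
perform cohort-component bookkeeping — the population model is
regression-based. Map rendering against real shapefiles is out of scope;
plotting is limited to trajectory fans (`autoplot`) and trace plots
(`plot_trace`).
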