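---
title: "Methods: Bayesian subnational estimation of MWRA counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian subnational estimation of MWRA counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The estimation problem

Counts of married women of reproductive age (MWRA, 15–49) by subnational
unit are the denominators of most reproductive-health indicators, but in
settings without a current population register they must be constructed
from heterogeneous sources: decennial-scale censuses, retrospective
fertility surveys, and national life tables. `mwrapop` implements a
regression-forecasting approach: the observed (log) MWRA count per single
age, division and census year is regressed on the three age-specific
demographic drivers of female population change — net migration, fertility
and survival — and the fitted relationship, combined with projected driver
values, yields out-of-sample probabilistic projections.

This vignette documents the models, their assumptions, the tunable
parameters, the numerical choices, and what the synthetic-data tests do and
do not demonstrate.

# The population model

For age $a$, division $d$ nested in region $r$, year $t$:

$$\log \eta_{adrt} \sim N(\log \eta^*_{adrt},\ \sigma^2), \qquad
\log \eta^*_{adrt} = \beta_0 + \beta_1 X_{1,adrt}
 + \beta_2 X_{2,adrt} X_{3,adrt} + u_{1,adt} + u_{2,drt}$$

where $X_1$ is the age proportion of net migration, $X_2$ the age-specific
fertility rate (ASFR), $X_3$ the single-age survival probability, and
$u_1, u_2$ zero-mean exchangeable normal varying effects over their index
sets. The observation model on log counts absorbs the residual term into a
single scale $\sigma$ — the only reading of a normally distributed
multiplicative error on counts that keeps the likelihood proper.
Assumptions worth stating plainly:

* the drivers act log-linearly on expected counts, with fertility and
  survival entering as an interaction (their product approximates the
  net reproduction contribution at each age);
* the coefficients are shared across cells ("estimating the $\beta$
  vectors" once), while cell-level heterogeneity is carried by $u_1, u_2$;
* census counts enter as person-weighted totals and are treated as
  error-free observations of the (noisy) true count.

**Identification.** Because every division lies in exactly one region,
$u_1$ is indexed at the observation level: the data identify only
$\sigma^2_{u1} + \sigma^2$ (monitored as `sigma_cell`), never the split.
Similarly, a free mean of $u_1$ or $u_2$ would trade off against
$\beta_0$. Both are handled structurally: the varying effects are centred
(sum-to-zero) within the sampler — they remain zero-mean draws marginally —
and the convergence flag is computed on identified functionals
($\beta$'s, `sigma_cell`, $\sigma_{u2}$, $u_2$, and the per-cell linear
predictor is monitored for prediction); the full diagnostics table still
reports every monitored parameter, with the unidentified split visibly
unmixed.

**Two-step forecasting.** Step one fits the model to the census years
(1976, 1987, 2005 in the default world). Step two predicts 2000–2030:
per retained draw, the linear predictor is evaluated at future covariates,
fresh varying effects are drawn from their posterior scales, and residual
noise is added, so parameter, heterogeneity and residual uncertainty all
propagate. Future covariates can be point values or per-draw matrices from
the driver models' posteriors; `run_pipeline()` pairs driver draws with
population draws index-wise (cyclically recycled when the chains have
different lengths). Pairing draw-wise, rather than integrating the driver
posterior first, preserves driver uncertainty in the projection intervals.

# Driver models

**Net migration.** Flows are computed from current vs previous division of
residence among MWRA; records with missing previous residence are treated
as non-migrants (contributing to neither flow), which preserves the
closed-system zero sum. Counts on historical registers are proportionally
partitioned onto the current register (`harmonize_counts()`), conserving
totals exactly. The age proportion $X_1 = \text{net}(a,d,t) / \sum_a
\text{net}(a,d,t)$ is normalised **within division**: the total in the
denominator is the division-year net, the reading of "net migration in age
group a / total net migration" consistent with the covariate's adrt index.
Mixed-sign age nets legitimately put $X_1$ outside $[0,1]$; when a
division-year total is exactly zero the proportion is undefined and is set
to 0 and flagged — asserting no age pattern rather than inventing a flow
direction. The smoothing model is Gaussian on the natural scale: a
random-walk level per region over calendar time (innovation variance
scaled by the gap between grid years), exchangeable division offsets
within regions, exchangeable age offsets within divisions, Gaussian
observation noise, half-normal priors on all four scales. This is the
simplest structure consistent with "single ages within divisions within
regions, in a time-series approach"; all scales are exposed in
`netmig_priors()` and any of them can be fixed, which makes the model a
linear-Gaussian state-space model with a closed-form posterior — used as
an independent oracle in the tests.

**Fertility.** `compute_asfr()` is a person-period estimator in the style
of `tfr2`: each woman's months inside the calendar window are assigned to
(single age, calendar year) cells by CMC arithmetic, exposure is weighted
months/12, births are allocated to the cell containing each child's birth
month, and the rate is weighted births over weighted woman-years. Months
strictly before the interview month count fully and the interview month
counts half; the month of reaching exact age $x$ is counted wholly at the
new age (the bias relative to a half-month birthday convention is below
half a month per woman per age, far inside the recovery tolerances used
here). Sampling weight and all-women factor multiply numerator and
denominator alike: constant factors cancel, woman-varying factors
re-weight the rate toward the full population of women — their purpose.
Cells with exposure but no births are genuine zeros; cells with no
exposure are `NA` and flagged, never zero. The smoothing model works on
log rates (positivity by construction): a shared random-walk age profile,
centred exchangeable region intercepts, and a per-region random walk over
time anchored at zero in the first grid year. Only cells with positive
births and exposure contribute likelihood terms; zero-birth cells shrink
to the hierarchy. The prior centre of the age profile is `log(0.02)`, a
weakly informative statement that fertility is low absent evidence — with
no data at all, posterior median rates stay below 0.05.

**Survival.** Abridged ₅pₓ values are anchored at age-group midpoints
($x + 2.5$) and period midpoints, interpolated linearly along age within
each period and then along calendar year, with linear extrapolation from
the end segments — the behaviour of Stata's `ipolate, epolate`, with
midpoint anchoring chosen because group-labelled interpolation leaves
anchor placement to the analyst. The default mode interpolates the
five-year probabilities *directly* into single-year values, reproducing
the source method; `mode = "fifth-root"` first takes $({}_5p_x)^{1/5}$,
the demographically standard conversion, and is offered as a correctness
flag. Results are clipped into $(0, 1]$ with the number of clipped cells
reported. Both age-then-year passes are linear, so the composition is
exact for bilinear inputs and reproduces all anchors.

# Posterior summaries and diagnostics

* Point estimates are **sums over ages (and nested units) of per-cell
  posterior medians**; intervals are 2.5th/97.5th percentiles of per-draw
  unit totals. The alternative median-of-sums is always reported alongside
  (for skewed draws it exceeds the sum of medians); the published
  convention is the default column.
* Percentiles use the type-7 (linear interpolation between order
  statistics) rule, verified against a sort-based oracle; the rule is a
  documented choice, not a claim about the source's software.
* The annual rate of change is $100 (P_{t_2} - P_{t_1}) / (P_{t_1}(t_2 -
  t_1))$, applied per draw and summarised by median and percentiles; a
  deterministic variant applies it to point medians. This definition
  reproduces the published regional rates from their printed endpoint
  medians at printed precision (East, Adamawa, South, and the national
  2020–2030 rate), which is how it was validated; the national 2000–2030
  published rate differs in the second decimal because it is a median of
  per-draw rates, not a rate of medians.
* R̂ is computed as $\sqrt{1 + B/(nW)}$ — the classical between/within
  variance ratio with the $(n-1)/n$ finite-sample factor dropped, so that
  identical chains give exactly 1 and the statistic is never below 1. It
  agrees with `coda::gelman.diag` to well under the 1.1 decision threshold
  on stationary chains, and the unsplit form matches the diagnostic as
  used in the Stata workflow being mirrored. Effective sample sizes come
  from `coda::effectiveSize`; for cell-level parameters ESS is computed on
  a subsample of columns (spectral estimation on thousands of columns buys
  little).
* Posterior predictive p-values simulate replicated log counts per draw
  from $N(\mu_s, \sigma_s)$ and report the fraction of draws whose
  replicated statistic is ≥ the observed one (statistics: mean, SD,
  maximum absolute residual); values outside (0.05, 0.95) flag misfit.
* The sensitivity harness re-fits with predictors excluded and with all
  prior scales multiplied by a factor, comparing division-year totals
  against baseline by median absolute and percentage difference. Under an
  unchanged configuration and the same seed the difference is exactly
  zero; on well-identified synthetic fits a ten-fold prior rescaling moves
  totals by well under 5%, the likelihood-domination check.

# Numerical choices

* **Scales** have half-normal priors truncated below at $10^{-4}$: when a
  posterior concentrates at zero variance (e.g. the random-walk innovation
  under a constant truth), an unbounded slice move can underflow the scale
  and overflow the implied precision. The floor is two orders of magnitude
  below any scale of scientific interest here.
* **Samplers.** All models are Gibbs-sampled through JAGS with fixed
  per-chain RNG seeds derived from the user seed (fully reproducible).
  The population model optionally uses JAGS's `glm` module, which
  block-updates all Gaussian latents: essential for weakly identified
  small frames, cubic in the latent count. The default `"auto"` setting
  uses blocked updates up to 400 cells and single-site conjugate updates
  above, where the data identify the coefficients strongly and single-site
  updates mix well.
* **Zero counts** are offset by +0.5 persons before logging and flagged —
  the log-scale likelihood requires positivity.
* **MCMC defaults** are 10,000 iterations per chain with burn-in 3,000 for
  the net-migration and population models and 5,000/3,000 for the
  fertility model, two chains. Tests and the acceptance script use
  reduced sizes (400–1,500 iterations, reduced worlds of 2 regions × 2–3
  divisions, 5–35 single ages), which the recovery results show are
  sufficient at those problem sizes.
* **Seeds.** Every stage derives its seed from the master seed by a fixed
  affine map modulo $2^{31}-1$ (`derive_seed()`), so stages are
  independently re-runnable and nothing depends on global RNG state.

# The synthetic world

The generator emulates the three restricted inputs with known ground
truth. Its cells satisfy the population model's identity *exactly*
(`log eta* = beta0 + beta1 X1 + beta2 X2 X3 + u1 + u2`), with a hump-shaped
migration age profile normalised to sum to one, a fertility schedule
peaking at age 27 with regional level shifts and a slow secular decline, a
survival surface declining in age and improving in time, and iid normal
u's with standard deviation `noise_sd` (default 0.05, a modest cell-level
heterogeneity). Census microdata are a 10% sample (person weight 10): the
number of sampled married women per cell is Poisson with mean
$\eta^*/10$, so weighted counts are unbiased for the truth; a log-normal
observation alternative is available. Unmarried women follow a
logistic-in-age proportion married (midpoint 20, scale 4 — a plausible
early-marriage schedule; the source gives none) and a male population of
matching size is included, so MWRA subsetting is genuinely exercised.
Movers receive a uniformly chosen other division as previous residence at
rate `migration_intensity` (default 0.05), and 2% of previous-residence
responses are missing. Birth histories are simulated month-by-month with
hazard ASFR/12. Defaults: censuses 1976/1987/2005, base cell population
400 (β₀ = log 400), β₁ = 1, β₂ = 1.5, ASFR peak 0.22, ₅pₓ level 0.98,
2,000 women per survey.

What the tests therefore show: the estimators recover their generating
quantities (flows exactly, a constant hazard to ±0.02 at 5,000 women,
coefficient and projection credible intervals with ≥86% empirical coverage
over 30 reduced-scale replicates) and the pipeline is deterministic and
internally coherent. What they do **not** show: robustness to real-data
features the generator omits — correlated covariates matching any real
country (the generator's fertility–survival correlation is incidental, not
calibrated), age heaping and misreporting, non-uniform migration
destination choice, survey nonresponse, parity-dependent birth spacing, or
boundary changes more complex than proportional splits.

# Known limitations

* Long-term internal migration only; the previous-residence question
  cannot separate recent from distant moves, and international migration
  is absent.
* The model is regression-based, not cohort-component: it does not enforce
  demographic accounting identities across ages and years, and projections
  inherit the assumption that the fitted driver–population relationship is
  stable over the projection horizon (only three census time points
  constrain it).
* The $u_1$/residual variance split is structurally unidentified (above);
  anything depending only on their sum is unaffected.
* Published credible intervals for unit totals could have been
  sums-of-percentiles or percentiles-of-sums; this package computes
  percentile-of-sums for intervals with sum-of-medians points, per the
  stated convention, and reports the alternative aggregation so users can
  compare.
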