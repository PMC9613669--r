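#' Priors for the regional ASFR model
#'
#' @param age_rw,time_rw,region,obs Half-normal prior scales for the
#'   age-profile random walk, the regional time random walk, the
#'   exchangeable region intercepts, and the log-scale observation noise.
#' @param center Prior centre of the log-rate at the first age; the
#'   default `log(0.02)` encodes a weak prior expectation of low fertility
#'   so that, absent data, posterior rates shrink towards small values.
#' @param fixed Optional named list fixing scales (see [netmig_priors()]).
#' @return A list of class `mwra_asfr_priors`.
#' @export
asfr_priors <- function(age_rw = 1, time_rw = 1, region = 1, obs = 1,
                        center = log(0.02), fixed = list()) {
  structure(list(age_rw = age_rw, time_rw = time_rw, region = region,
                 obs = obs, center = center, fixed = fixed),
            class = "mwra_asfr_priors")
}

#' Bayesian hierarchical model for regional age-specific fertility rates
#'
#' Smooths, interpolates and extrapolates single-age ASFR over regions and
#' calendar years on the log scale (so rates are positive by
#' construction): an age profile shared across regions evolves as a random
#' walk over single ages, regions deviate through exchangeable intercepts,
#' and each region carries a random-walk level over calendar time
#' (anchored at zero in the first grid year, variance scaled by year
#' gaps). Empirical cells with positive exposure and at least one birth
#' contribute `log(asfr)` observations with Gaussian noise; zero-birth and
#' zero-exposure cells carry no likelihood and are imputed from the
#' hierarchy, as are all projection years.
#'
#' @param surface Empirical ASFR surface from [compute_asfr()] (columns
#'   `age`, `region`, `year`, `asfr`, `exposure`, `births`), or any tibble
#'   with those columns.
#' @param years Calendar years of the output grid; defaults to the
#'   observed years plus 1976-2030.
#' @param settings [mcmc_settings()]; the study default for fertility is
#'   5,000 draws with burn-in 3,000.
#' @param priors [asfr_priors()].
#' @return An object of class `mwra_asfr_fit` (and `mwra_fit`); extract
#'   rates with [covariate_medians()] / [covariate_draws()] (returned on
#'   the natural rate scale).
#' @export
fit_asfr_model <- function(surface, years = NULL,
                           settings = mcmc_settings(n_draws = 5000),
                           priors = asfr_priors()) {
  req <- c("age", "region", "year", "asfr")
  if (!all(req %in% names(surface))) {
    rlang::abort(sprintf("ASFR surface needs columns %s", paste(req, collapse = ", ")))
  }
  obs <- dplyr::filter(surface, !is.na(.data$asfr), .data$asfr > 0)
  obs_years <- sort(unique(surface$year))
  years <- sort(unique(c(obs_years, years %||% 1976:2030)))
  ages <- sort(unique(surface$age))
  regions <- sort(unique(surface$region))
  A <- length(ages); R <- length(regions); K <- length(years)

  f <- priors$fixed
  likelihood <- if (nrow(obs) > 0) {
    "  for (i in 1:N) { y[i] ~ dnorm(mu[age_i[i], reg_i[i], k_i[i]], tau_obs) }\n"
  } else ""
  model_string <- paste0(
    "model {\n",
    sprintf("  gamma[1] ~ dnorm(%.10g, 1)\n", priors$center),
    "  for (a in 2:A) { gamma[a] ~ dnorm(gamma[a-1], tau_agerw) }\n",
    # region intercepts centred so the age random walk carries the level
    "  for (r in 1:R) { braw[r] ~ dnorm(0, tau_reg) }\n",
    "  for (r in 1:R) {\n",
    "    b[r] <- braw[r] - mean(braw)\n",
    "    psi[r,1] <- 0\n",
    "    for (k in 2:K) { psi[r,k] ~ dnorm(psi[r,k-1], tau_rw / gap[k]) }\n",
    "    for (a in 1:A) { for (k in 1:K) { mu[a,r,k] <- gamma[a] + b[r] + psi[r,k] } }\n",
    "  }\n",
    likelihood,
    scale_node("sigma_agerw", priors$age_rw, f$age_rw), "\n",
    scale_node("sigma_rw", priors$time_rw, f$time_rw), "\n",
    scale_node("sigma_reg", priors$region, f$region), "\n",
    scale_node("sigma_obs", priors$obs, f$obs), "\n",
    "}\n")

  data <- list(A = A, R = R, K = K, gap = c(1, diff(years)))
  if (nrow(obs) > 0) {
    data$N <- nrow(obs)
    data$y <- log(obs$asfr)
    data$age_i <- match(obs$age, ages)
    data$reg_i <- match(obs$region, regions)
    data$k_i <- match(obs$year, years)
  }
  monitor <- c("mu", "gamma", "sigma_agerw", "sigma_rw", "sigma_reg", "sigma_obs")
  monitor <- setdiff(monitor, paste0("sigma_", c(age_rw = "agerw", time_rw = "rw",
                                                 region = "reg", obs = "obs")[names(f)]))
  draws <- jags_sample(model_string, data, monitor, settings,
                       inits = scale_inits(priors, c(age_rw = "sigma_agerw",
                                                     time_rw = "sigma_rw",
                                                     region = "sigma_reg",
                                                     obs = "sigma_obs")))

  grid <- tibble::tibble(
    term = sprintf("mu[%d,%d,%d]",
                   rep(seq_len(A), times = R * K),
                   rep(rep(seq_len(R), each = A), times = K),
                   rep(seq_len(K), each = A * R)),
    age = rep(ages, times = R * K),
    region = rep(rep(regions, each = A), times = K),
    year = rep(years, each = A * R)
  )
  diag <- convergence_table(draws)
  converged <- flag_convergence(diag, "fertility model")
  structure(list(draws = draws, grid = grid, years = years,
                 observed_years = obs_years, settings = settings,
                 priors = priors, diagnostics = diag, converged = converged,
                 model_string = model_string, kind = "fertility"),
            class = c("mwra_asfr_fit", "mwra_fit"))
}
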