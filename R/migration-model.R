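#' Priors for the net-migration proportion model
#'
#' Weakly-informative half-normal priors on all scale parameters, with the
#' option to fix any scale at a known value (`fixed`), which turns the
#' model into a linear-Gaussian state-space model with a closed-form
#' posterior - useful for validation.
#'
#' @param rw,division,age,obs Half-normal prior scales for the random-walk
#'   innovation, division offsets, age offsets and observation noise.
#' @param level_sd Prior standard deviation of each region's initial level.
#' @param fixed Optional named list fixing scales, e.g.
#'   `list(obs = 0.02, rw = 0.01)`.
#' @return A list of class `mwra_netmig_priors`.
#' @export
netmig_priors <- function(rw = 1, division = 1, age = 1, obs = 1,
                          level_sd = 10, fixed = list()) {
  structure(list(rw = rw, division = division, age = age, obs = obs,
                 level_sd = level_sd, fixed = fixed),
            class = "mwra_netmig_priors")
}

#' Bayesian hierarchical time-series model for net-migration proportions
#'
#' Smooths and extrapolates the age proportions of net migration (the X1
#' covariate of the population model) with a Gaussian hierarchical
#' structure mirroring the nesting of single ages within divisions and
#' divisions within regions, evolving over time: each region carries a
#' random-walk level over calendar time (variance scaled by the gap
#' between grid years), divisions deviate from their region through
#' exchangeable offsets, and ages within divisions through further
#' exchangeable offsets. Observed proportions at census years enter with
#' Gaussian noise; all other grid years (including the projection span)
#' are treated as missing and imputed from the posterior. Proportions are
#' modelled on their natural scale, so posterior values may lie outside
#' \[0, 1\] exactly as empirical mixed-sign proportions may.
#'
#' @param series Output of [age_proportions()] (needs columns
#'   `census_year`, `division`, `age`, `X1`).
#' @param register Administrative register.
#' @param years Calendar years of the output grid; defaults to the
#'   observed census years plus 2000-2030.
#' @param settings [mcmc_settings()]; the study default is 10,000 draws
#'   with burn-in 3,000.
#' @param priors [netmig_priors()].
#' @return An object of class `mwra_netmig_fit` (and `mwra_fit`):
#'   posterior draws of the smoothed proportion for every (age, division,
#'   year), scale parameters, and convergence diagnostics. Non-convergence
#'   (R-hat >= 1.1) is surfaced as a warning, never an error.
#' @export
fit_netmigration_model <- function(series, register,
                                   years = NULL,
                                   settings = mcmc_settings(),
                                   priors = netmig_priors()) {
  register <- validate_register(register)
  obs_years <- sort(unique(series$census_year))
  if (length(obs_years) < 2) {
    rlang::abort("need at least 2 observed time points", class = "mwrapop_validation_error")
  }
  years <- sort(unique(c(obs_years, years %||% 2000:2030)))
  ages <- sort(unique(series$age))
  divisions <- register$division[register$division %in% unique(series$division)]
  regions <- unique(register$region[match(divisions, register$division)])

  A <- length(ages); D <- length(divisions); K <- length(years)
  x <- array(NA_real_, dim = c(A, D, K))
  sel <- series$division %in% divisions
  x[cbind(match(series$age[sel], ages), match(series$division[sel], divisions),
          match(series$census_year[sel], years))] <- series$X1[sel]

  f <- priors$fixed
  model_string <- paste0(
    "model {\n",
    "  for (r in 1:R) {\n",
    sprintf("    phi[r,1] ~ dnorm(0, %.10g)\n", 1 / priors$level_sd^2),
    "    for (k in 2:K) { phi[r,k] ~ dnorm(phi[r,k-1], tau_rw / gap[k]) }\n",
    "  }\n",
    # division and age offsets are centred (sum-to-zero) so the regional
    # random-walk level is identified as the mean trajectory
    "  for (d in 1:D) { deltaraw[d] ~ dnorm(0, tau_div) }\n",
    "  for (d in 1:D) {\n",
    "    delta[d] <- deltaraw[d] - mean(deltaraw)\n",
    "    for (a in 1:A) { alpharaw[a,d] ~ dnorm(0, tau_age) }\n",
    "    for (a in 1:A) { alpha[a,d] <- alpharaw[a,d] - mean(alpharaw[1:A,d]) }\n",
    "    for (a in 1:A) { for (k in 1:K) {\n",
    "      theta[a,d,k] <- phi[reg[d],k] + delta[d] + alpha[a,d]\n",
    "      x[a,d,k] ~ dnorm(theta[a,d,k], tau_obs)\n",
    "    }}\n",
    "  }\n",
    scale_node("sigma_rw", priors$rw, f$rw), "\n",
    scale_node("sigma_div", priors$division, f$division), "\n",
    scale_node("sigma_age", priors$age, f$age), "\n",
    scale_node("sigma_obs", priors$obs, f$obs), "\n",
    "}\n")

  data <- list(x = x, R = length(regions), D = D, A = A, K = K,
               reg = match(register$region[match(divisions, register$division)], regions),
               gap = c(1, diff(years)))
  monitor <- c("theta", "sigma_rw", "sigma_div", "sigma_age", "sigma_obs")
  monitor <- setdiff(monitor, paste0("sigma_", names(f)))
  draws <- jags_sample(model_string, data, monitor, settings,
                       inits = scale_inits(priors, c(rw = "sigma_rw",
                                                     division = "sigma_div",
                                                     age = "sigma_age",
                                                     obs = "sigma_obs")))

  grid <- tibble::tibble(
    term = sprintf("theta[%d,%d,%d]",
                   rep(seq_len(A), times = D * K),
                   rep(rep(seq_len(D), each = A), times = K),
                   rep(seq_len(K), each = A * D)),
    age = rep(ages, times = D * K),
    division = rep(rep(divisions, each = A), times = K),
    year = rep(years, each = A * D)
  )
  grid$region <- register$region[match(grid$division, register$division)]

  diag <- convergence_table(draws)
  converged <- flag_convergence(diag, "net-migration model")
  structure(list(draws = draws, grid = grid, years = years,
                 observed_years = obs_years, settings = settings,
                 priors = priors, diagnostics = diag, converged = converged,
                 model_string = model_string, kind = "net-migration"),
            class = c("mwra_netmig_fit", "mwra_fit"))
}

#' Posterior summaries and draws of a fitted covariate surface
#'
#' `covariate_medians()` returns the posterior median and 95% credible
#' interval of the modelled covariate on its output grid (net-migration
#' proportion X1, or ASFR X2 on the natural scale for fertility fits).
#' `covariate_draws()` returns the draws matrix (retained draws x cells)
#' aligned with the rows of `cells`, used to pair driver-model uncertainty
#' with the population model draw-by-draw.
#'
#' @param fit A `mwra_netmig_fit` or `mwra_asfr_fit`.
#' @param cells Tibble of cells to extract (columns matching the fit's
#'   grid keys); defaults to the full grid.
#' @return A tibble (`covariate_medians`) or numeric matrix
#'   (`covariate_draws`).
#' @export
covariate_medians <- function(fit, cells = NULL) {
  grid <- if (is.null(cells)) fit$grid else join_grid(fit, cells)
  s <- draws_summary(fit$draws, terms = grid$term)
  dplyr::bind_cols(grid[match(s$term, grid$term),
                        setdiff(names(grid), "term")], s[-1]) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(c("median", "cri_low", "cri_high")),
                                if (fit$kind == "fertility") exp else identity))
}

#' @rdname covariate_medians
#' @export
covariate_draws <- function(fit, cells) {
  grid <- join_grid(fit, cells)
  m <- draws_matrix(fit$draws)[, grid$term, drop = FALSE]
  if (fit$kind == "fertility") exp(m) else m
}

join_grid <- function(fit, cells) {
  keys <- intersect(names(fit$grid), names(cells))
  keys <- setdiff(keys, "term")
  out <- dplyr::left_join(cells[, keys], fit$grid,
                          by = keys, relationship = "many-to-one")
  if (anyNA(out$term)) {
    miss <- out[is.na(out$term), keys]
    rlang::abort(sprintf("fit does not cover %d requested cell(s), e.g. %s",
                         nrow(miss), paste(unlist(miss[1, ]), collapse = "/")),
                 class = "mwrapop_coverage_error")
  }
  out
}
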