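#' Weighted married-women counts from census microdata
#'
#' Person-weighted counts of married women of reproductive age per (age,
#' division, census year), the outcome variable of the population model.
#'
#' @param records Census person records (see [generate_census()]).
#' @param register Administrative register.
#' @param ages Ages retained.
#' @return A tibble with columns `year`, `division`, `age`, `count` (grid
#'   completed with zeros).
#' @export
census_mwra_counts <- function(records, register, ages = 15:49) {
  register <- validate_register(register)
  check_divisions(records$division_current, register, "current division")
  records |>
    dplyr::filter(.data$sex == "female", .data$marital_status == "married",
                  .data$age %in% ages) |>
    dplyr::group_by(year = .data$census_year, division = .data$division_current,
                    age = .data$age) |>
    dplyr::summarise(count = sum(.data$person_weight), .groups = "drop") |>
    dplyr::right_join(tidyr::expand_grid(year = sort(unique(records$census_year)),
                                         division = register$division,
                                         age = sort(as.integer(ages))),
                      by = c("year", "division", "age")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0)) |>
    dplyr::arrange(.data$year, .data$division, .data$age)
}

#' Assemble the population-model frame
#'
#' Joins the outcome (weighted married-women counts per age, division,
#' year) with the three demographic drivers: X1 the net-migration age
#' proportion (by age, division, year), X2 the age-specific fertility rate
#' (regional, broadcast to the region's divisions), and X3 the single-age
#' survival probability (national, broadcast to all units). Counts of zero
#' are offset by +0.5 persons before logging (flagged in `log_offset`)
#' since the likelihood lives on the log scale. The pairwise Pearson
#' correlations of the covariates - a linearity/collinearity diagnostic
#' for the regression forecasting set-up, notably between fertility and
#' survival - are attached as attribute `covariate_correlations` (entries
#' are `NA` and flagged when a covariate is constant).
#'
#' @param counts Tibble `year`, `division`, `age`, `count` (e.g. from
#'   [census_mwra_counts()]).
#' @param migration_series Tibble with `age`, `division`, `year` (or
#'   `census_year`) and `X1` (e.g. from [age_proportions()] or
#'   [covariate_medians()] of a net-migration fit).
#' @param asfr_surface Tibble with `age`, `region`, `year` and `asfr` (or
#'   `X2`/`median`).
#' @param survival_surface Tibble with `age`, `year` and `px1` (or `X3`).
#' @param register Administrative register.
#' @return A tibble of class `mwra_model_frame` with columns `age`,
#'   `division`, `region`, `year`, `count`, `log_count`, `log_offset`,
#'   `X1`, `X2`, `X3`, `X2X3`.
#' @export
build_frame <- function(counts, migration_series, asfr_surface,
                        survival_surface, register) {
  register <- validate_register(register)
  pick <- function(x, candidates, label) {
    nm <- intersect(candidates, names(x))
    if (!length(nm)) {
      rlang::abort(sprintf("%s must contain one of: %s", label,
                           paste(candidates, collapse = ", ")))
    }
    nm[1]
  }
  mig <- migration_series
  if (!"year" %in% names(mig) && "census_year" %in% names(mig)) {
    mig <- dplyr::rename(mig, year = "census_year")
  }
  x1col <- pick(mig, c("X1", "median", "prop_net"), "migration_series")
  x2col <- pick(asfr_surface, c("asfr", "X2", "median"), "asfr_surface")
  x3col <- pick(survival_surface, c("px1", "X3", "median"), "survival_surface")

  frame <- counts |>
    dplyr::left_join(register, by = "division") |>
    dplyr::left_join(dplyr::select(mig, "age", "division", "year", X1 = dplyr::all_of(x1col)),
                     by = c("age", "division", "year")) |>
    dplyr::left_join(dplyr::select(asfr_surface, "age", "region", "year",
                                   X2 = dplyr::all_of(x2col)),
                     by = c("age", "region", "year")) |>
    dplyr::left_join(dplyr::select(survival_surface, "age", "year",
                                   X3 = dplyr::all_of(x3col)),
                     by = c("age", "year"))

  miss <- frame[!stats::complete.cases(frame[, c("X1", "X2", "X3")]), ]
  if (nrow(miss)) {
    cols <- c("X1", "X2", "X3")[c(anyNA(frame$X1), anyNA(frame$X2), anyNA(frame$X3))]
    ex <- miss[seq_len(min(3, nrow(miss))), c("age", "division", "year")]
    rlang::abort(sprintf(
      "covariate coverage error: %d cell(s) missing %s after join, e.g. %s",
      nrow(miss), paste(cols, collapse = "/"),
      paste(apply(ex, 1, paste, collapse = "/"), collapse = "; ")),
      class = "mwrapop_coverage_error")
  }

  frame <- frame |>
    dplyr::mutate(log_offset = .data$count == 0,
                  log_count = log(.data$count + 0.5 * (.data$count == 0)),
                  X2X3 = .data$X2 * .data$X3) |>
    dplyr::select("age", "division", "region", "year", "count", "log_count",
                  "log_offset", "X1", "X2", "X3", "X2X3")
  if (any(frame$log_offset)) {
    rlang::warn(sprintf("%d zero count(s) offset by +0.5 before logging",
                        sum(frame$log_offset)))
  }

  safe_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
  }
  cors <- tibble::tibble(
    pair = c("X1~X2", "X1~X3", "X2~X3", "X1~X2X3"),
    r = c(safe_cor(frame$X1, frame$X2), safe_cor(frame$X1, frame$X3),
          safe_cor(frame$X2, frame$X3), safe_cor(frame$X1, frame$X2X3)))
  cors$constant <- is.na(cors$r)
  attr(frame, "covariate_correlations") <- cors
  class(frame) <- c("mwra_model_frame", class(frame))
  frame
}

#' Priors and structure of the population model
#'
#' @param beta_sd Normal prior standard deviation of the regression
#'   coefficients (intercept, net-migration effect, fertility-x-survival
#'   effect).
#' @param u1,u2,obs Half-normal prior scales for the age-division-year
#'   varying effect, the division-year varying effect, and the residual
#'   observation scale on log counts.
#' @param fixed Optional named list fixing scales.
#' @return A list of class `mwra_pop_priors`.
#' @export
pop_priors <- function(beta_sd = 10, u1 = 1, u2 = 1, obs = 1, fixed = list()) {
  structure(list(beta_sd = beta_sd, u1 = u1, u2 = u2, obs = obs, fixed = fixed),
            class = "mwra_pop_priors")
}

# rescale every prior scale by a common factor (sensitivity analysis)
scale_priors <- function(priors, factor) {
  priors$beta_sd <- priors$beta_sd * factor
  priors$u1 <- priors$u1 * factor
  priors$u2 <- priors$u2 * factor
  priors$obs <- priors$obs * factor
  priors
}

#' Fit the hierarchical log-linear population model
#'
#' Step one of the regression forecasting approach. The observed
#' log-counts follow
#' `log(eta) ~ Normal(log(eta*), sigma^2)` with linear predictor
#' `log(eta*) = beta0 + beta1 * X1 + beta2 * X2 * X3 + u1[age, division, year] + u2[division, year]`,
#' where X1 is the net-migration age proportion, X2 the age-specific
#' fertility rate, X3 the survival probability, u1 and u2 are zero-mean
#' exchangeable normal varying effects over their index sets, and the
#' residual is absorbed in the observation scale sigma. Coefficients get
#' Normal(0, `beta_sd`^2) priors and all scales half-normal priors.
#'
#' @param frame A [build_frame()] result with at least 2 census years.
#' @param settings [mcmc_settings()]; study default 10,000 draws, burn-in
#'   3,000.
#' @param priors [pop_priors()].
#' @param drop Character vector of predictors to exclude (any of `"X1"`,
#'   `"X2X3"`); used by the sensitivity analysis. Dropped coefficients are
#'   fixed at zero.
#' @param prior_only If `TRUE`, the outcome is treated as unobserved and
#'   the sampler draws from the prior (a sampler-correctness check).
#' @return An object of class `mwra_pop_fit` (and `mwra_fit`) holding
#'   draws of `beta0`, `beta1`, `beta2`, the scales, all varying effects,
#'   and the in-sample linear predictor `mu` per frame row, plus
#'   convergence diagnostics. Non-convergence is flagged with a warning.
#'   Because u1 is indexed at the observation level alongside the
#'   residual, only the sum of their variances (`sigma_cell`) is
#'   identified; the diagnostics table marks identified functionals and
#'   the convergence flag is computed on those.
#' @export
fit_population_model <- function(frame, settings = mcmc_settings(),
                                 priors = pop_priors(), drop = character(),
                                 prior_only = FALSE) {
  if (nrow(frame) < 2) {
    rlang::abort("degenerate frame: need more than one cell",
                 class = "mwrapop_validation_error")
  }
  if (length(unique(frame$year)) < 2) {
    rlang::abort("need at least 2 census time points",
                 class = "mwrapop_validation_error")
  }
  stopifnot(all(drop %in% c("X1", "X2X3")))

  u1_keys <- dplyr::distinct(frame, .data$age, .data$division, .data$year)
  u2_keys <- dplyr::distinct(frame, .data$division, .data$year)
  j1 <- dplyr::left_join(frame, dplyr::mutate(u1_keys, .j = dplyr::row_number()),
                         by = c("age", "division", "year"))$.j
  j2 <- dplyr::left_join(frame, dplyr::mutate(u2_keys, .j = dplyr::row_number()),
                         by = c("division", "year"))$.j

  f <- priors$fixed
  beta_prec <- 1 / priors$beta_sd^2
  b1 <- if ("X1" %in% drop) "  beta1 <- 0\n" else
    sprintf("  beta1 ~ dnorm(0, %.10g)\n", beta_prec)
  b2 <- if ("X2X3" %in% drop) "  beta2 <- 0\n" else
    sprintf("  beta2 ~ dnorm(0, %.10g)\n", beta_prec)
  model_string <- paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    "    mu[i] <- beta0 + beta1 * x1[i] + beta2 * x23[i] + u1[j1[i]] + u2[j2[i]]\n",
    "    y[i] ~ dnorm(mu[i], tau_obs)\n",
    "  }\n",
    # sum-to-zero centering identifies the intercept against the
    # exchangeable varying effects (they remain zero-mean marginally)
    "  for (j in 1:N1) { u1raw[j] ~ dnorm(0, tau_u1) }\n",
    "  for (j in 1:N2) { u2raw[j] ~ dnorm(0, tau_u2) }\n",
    "  for (j in 1:N1) { u1[j] <- u1raw[j] - mean(u1raw) }\n",
    "  for (j in 1:N2) { u2[j] <- u2raw[j] - mean(u2raw) }\n",
    sprintf("  beta0 ~ dnorm(0, %.10g)\n", beta_prec),
    b1, b2,
    scale_node("sigma_obs", priors$obs, f$obs), "\n",
    scale_node("sigma_u1", priors$u1, f$u1), "\n",
    scale_node("sigma_u2", priors$u2, f$u2), "\n",
    "  sigma_cell <- sqrt(pow(sigma_obs, 2) + pow(sigma_u1, 2))\n",
    "}\n")

  data <- list(N = nrow(frame), N1 = nrow(u1_keys), N2 = nrow(u2_keys),
               x1 = frame$X1, x23 = frame$X2X3, j1 = j1, j2 = j2)
  if (!prior_only) data$y <- frame$log_count

  monitor <- c("beta0", "beta1", "beta2", "sigma_obs", "sigma_u1", "sigma_u2",
               "sigma_cell", "u1", "u2", "mu")
  monitor <- setdiff(monitor, c(paste0("sigma_", names(f)),
                                if ("X1" %in% drop) "beta1",
                                if ("X2X3" %in% drop) "beta2"))
  use_glm <- switch(settings$sampler %||% "auto",
                    "blocked-glm" = TRUE, "conjugate" = FALSE,
                    nrow(frame) <= 400)
  draws <- jags_sample(model_string, data, monitor, settings, use_glm = use_glm,
                       inits = scale_inits(priors, c(obs = "sigma_obs",
                                                     u1 = "sigma_u1",
                                                     u2 = "sigma_u2")))

  diag <- convergence_table(draws)
  # the split between the observation-level varying effect u1 and the
  # residual is not identified by the data (only their sum is); the
  # convergence flag therefore assesses identified functionals, while the
  # full table still reports every monitored parameter
  diag$identified <- grepl("^beta|^sigma_cell$|^sigma_u2$|^u2\\[", diag$term)
  converged <- flag_convergence(diag[diag$identified, ], "population model")
  structure(list(draws = draws, frame = frame, u1_keys = u1_keys,
                 u2_keys = u2_keys, settings = settings, priors = priors,
                 drop = drop, prior_only = prior_only, diagnostics = diag,
                 converged = converged, model_string = model_string,
                 kind = "population"),
            class = c("mwra_pop_fit", "mwra_fit"))
}

#' @export
print.mwra_fit <- function(x, ...) {
  cat(sprintf("<%s> %s model fit: %d draws, converged: %s\n",
              class(x)[1], x$kind, n_draws_total(x$draws), x$converged))
  invisible(x)
}

# extract a scalar parameter's draws (0 if dropped from the model)
param_draws <- function(fit, name) {
  m <- draws_matrix(fit$draws)
  if (name %in% colnames(m)) m[, name] else {
    fx <- switch(name, sigma_obs = fit$priors$fixed$obs,
                 sigma_u1 = fit$priors$fixed$u1, sigma_u2 = fit$priors$fixed$u2,
                 NULL)
    rep(fx %||% 0, nrow(m))
  }
}

#' Project populations out of sample (step two)
#'
#' Given the fitted coefficient and scale draws, predicts counts for new
#' (age, division, year) cells from future covariate values: per retained
#' draw s,
#' `log(eta) = beta0_s + beta1_s * X1 + beta2_s * X2 * X3 + u1 + u2 (+ eps)`,
#' with fresh varying effects `u1 ~ N(0, sigma_u1_s)` per (age, division,
#' year), `u2 ~ N(0, sigma_u2_s)` per (division, year), and residual
#' `eps ~ N(0, sigma_s)` per cell - so parameter, varying-effect and
#' residual uncertainty all propagate. Future covariates may be supplied
#' as point values in `newdata`, or as per-draw matrices (`x1_draws`,
#' `x2_draws`, `x3_draws`, columns aligned with `newdata` rows) taken from
#' the driver models' posteriors and paired draw-by-draw, so driver
#' uncertainty propagates too.
#'
#' @param fit A [fit_population_model()] result.
#' @param newdata Tibble with columns `age`, `division`, `region`, `year`
#'   and (unless draw matrices are given) `X1`, `X2`, `X3`.
#' @param x1_draws,x2_draws,x3_draws Optional matrices (rows = retained
#'   population-model draws, recycled cyclically if the driver fit has a
#'   different draw count; columns = `newdata` rows).
#' @param include_u,include_residual Include fresh varying effects /
#'   residual noise (disable to study the deterministic linear predictor).
#' @param seed Integer seed for the fresh effects (deterministic
#'   projection).
#' @return An object of class `mwra_projection_draws`: list with `counts`
#'   (draws x cells matrix), `cells`, and the originating chain index.
#' @export
project_population <- function(fit, newdata, x1_draws = NULL, x2_draws = NULL,
                               x3_draws = NULL, include_u = TRUE,
                               include_residual = TRUE, seed = 1L) {
  stopifnot(inherits(fit, "mwra_pop_fit"))
  n <- nrow(newdata)
  S <- n_draws_total(fit$draws)
  need_pt <- c(if (is.null(x1_draws)) "X1", if (is.null(x2_draws)) "X2",
               if (is.null(x3_draws)) "X3")
  if (!all(need_pt %in% names(newdata))) {
    rlang::abort(sprintf("newdata must provide covariate column(s): %s",
                         paste(setdiff(need_pt, names(newdata)), collapse = ", ")),
                 class = "mwrapop_coverage_error")
  }
  if (anyNA(newdata[, intersect(need_pt, names(newdata))])) {
    rlang::abort("missing future covariate values in newdata",
                 class = "mwrapop_coverage_error")
  }
  recycle <- function(m) {
    if (is.null(m)) return(NULL)
    stopifnot(ncol(m) == n)
    m[((seq_len(S) - 1) %% nrow(m)) + 1, , drop = FALSE]
  }
  X1 <- recycle(x1_draws) %||% matrix(newdata$X1, S, n, byrow = TRUE)
  X2 <- recycle(x2_draws) %||% matrix(newdata$X2, S, n, byrow = TRUE)
  X3 <- recycle(x3_draws) %||% matrix(newdata$X3, S, n, byrow = TRUE)

  beta0 <- param_draws(fit, "beta0")
  beta1 <- param_draws(fit, "beta1")
  beta2 <- param_draws(fit, "beta2")
  sigma_obs <- param_draws(fit, "sigma_obs")
  sigma_u1 <- param_draws(fit, "sigma_u1")
  sigma_u2 <- param_draws(fit, "sigma_u2")

  log_eta <- beta0 + beta1 * X1 + beta2 * X2 * X3

  u1_keys <- dplyr::distinct(newdata, .data$age, .data$division, .data$year)
  u2_keys <- dplyr::distinct(newdata, .data$division, .data$year)
  k1 <- dplyr::left_join(newdata, dplyr::mutate(u1_keys, .j = dplyr::row_number()),
                         by = c("age", "division", "year"))$.j
  k2 <- dplyr::left_join(newdata, dplyr::mutate(u2_keys, .j = dplyr::row_number()),
                         by = c("division", "year"))$.j
  with_seed(seed, {
    if (include_u) {
      u1 <- matrix(rnorm(S * nrow(u1_keys)), S) * sigma_u1
      u2 <- matrix(rnorm(S * nrow(u2_keys)), S) * sigma_u2
      log_eta <- log_eta + u1[, k1, drop = FALSE] + u2[, k2, drop = FALSE]
    }
    if (include_residual) {
      log_eta <- log_eta + matrix(rnorm(S * n), S) * sigma_obs
    }
  })
  structure(list(counts = exp(log_eta),
                 cells = tibble::as_tibble(newdata[, c("age", "division", "region", "year")]),
                 chain = fit$draws$chain),
            class = "mwra_projection_draws")
}

#' @export
print.mwra_projection_draws <- function(x, ...) {
  cat(sprintf("<mwra_projection_draws> %d draws x %d cells (years %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(range(x$cells$year), collapse = "-")))
  invisible(x)
}
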