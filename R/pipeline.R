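#' Run the full estimation pipeline
#'
#' Orchestrates the end-to-end run on a synthetic world: simulate ->
#' migration (flows, optional boundary harmonization, age proportions,
#' Bayesian smoothing) -> fertility (ASFR estimation and Bayesian
#' smoothing) -> survival interpolation -> population model fit ->
#' out-of-sample projection with driver posteriors paired draw-by-draw ->
#' summaries, rates, diagnostics and (optionally) sensitivity analysis.
#' All artifacts are written as CSV/JSON under `out_dir` together with a
#' manifest recording per-stage seeds and file checksums. Per-stage seeds
#' are derived deterministically from the master seed (see
#' [derive_seed()]), so the run is reproducible end to end and stages can
#' be re-run independently.
#'
#' @param config A named list or the path of a YAML file. Recognised
#'   entries (all optional except `out_dir`): `seed`; `world` (arguments
#'   to [world_config()]); `window` (fertility estimation years, default
#'   the 10 years up to the last census); `projection_years` (default
#'   2000:2030); `harmonize` plus `partition_map` (path or data frame);
#'   `survival_mode`; `mcmc` with sub-lists `netmig`, `fertility`,
#'   `population` (defaults: 10,000 draws burn-in 3,000 for net-migration
#'   and population, 5,000/3,000 for fertility); `rate_periods` (list of
#'   year pairs); `sensitivity` (`enabled`, `prior_scale_factors`,
#'   `drop_sets`).
#' @return (Invisibly) a list with the in-memory results of every stage
#'   plus `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) config_error("out_dir", "must be given")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  proj_years <- as.integer(config$projection_years %||% 2000:2030)
  if (is.unsorted(proj_years)) config_error("projection_years", "must be ordered")

  stage_seed <- function(i) derive_seed(seed, i)
  msg <- function(stage, ...) message(sprintf("[%s] %s", stage, sprintf(...)))
  files <- character()
  put_csv <- function(x, name) {
    path <- file.path(config$out_dir, name)
    readr::write_csv(x, path)
    files[[name]] <<- path
  }
  put_json <- function(x, name) {
    path <- file.path(config$out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "columns")
    files[[name]] <<- path
  }
  mc <- function(which, default_draws) {
    args <- config$mcmc[[which]] %||% list()
    mcmc_settings(n_draws = args$n_draws %||% default_draws,
                  burn_in = args$burn_in %||% 3000,
                  n_chains = args$n_chains %||% 2,
                  seed = stage_seed(args$seed_offset %||% switch(which,
                    netmig = 20L, fertility = 30L, population = 40L)))
  }

  # -- simulate ---------------------------------------------------------
  msg("simulate", "building synthetic world")
  wargs <- config$world %||% list()
  wargs$seed <- wargs$seed %||% stage_seed(10L)
  cfg <- do.call(world_config, wargs)
  truth <- ground_truth(cfg, years = sort(unique(c(cfg$census_years, proj_years))))
  census <- generate_census(cfg, truth)
  births <- generate_birth_histories(cfg, truth_asfr_surface(truth))
  lifetable <- generate_life_tables(cfg)
  put_csv(census, "census.csv")
  put_csv(dplyr::mutate(births, child_birth_cmcs = vapply(
    .data$child_birth_cmcs, paste, "", collapse = ";")), "births.csv")
  put_csv(lifetable, "lifetable.csv")
  put_json(list(betas = as.list(truth$betas), cells = truth$cells), "truth.json")

  # -- migration --------------------------------------------------------
  msg("migration", "computing flows and age proportions")
  flows <- compute_flows(census, cfg$register, ages = cfg$ages)
  if (isTRUE(config$harmonize)) {
    if (is.null(config$partition_map)) {
      rlang::abort("stage migration failed: `partition_map` is required when harmonize = TRUE",
                   class = "mwrapop_config_error")
    }
    map <- if (is.character(config$partition_map)) {
      readr::read_csv(config$partition_map, show_col_types = FALSE)
    } else tibble::as_tibble(config$partition_map)
    flows <- harmonize_flows(flows, map)
    flows <- dplyr::left_join(flows, cfg$register, by = "division")
  }
  mig_series <- age_proportions(flows)
  put_csv(mig_series, "migration_series.csv")
  msg("migration", "fitting net-migration model")
  netmig_fit <- fit_netmigration_model(mig_series, cfg$register,
                                       years = proj_years,
                                       settings = mc("netmig", 10000))
  netmig_med <- covariate_medians(netmig_fit)
  put_json(list(medians = netmig_med, parameters = tidy(netmig_fit)),
           "netmig_posterior.json")

  # -- fertility --------------------------------------------------------
  window <- config$window %||% c(max(cfg$census_years) - 9, max(cfg$census_years))
  msg("fertility", "estimating ASFR over %d-%d", window[1], window[2])
  asfr_emp <- compute_asfr(births, window = window, ages = cfg$ages)
  put_csv(asfr_emp, "asfr_empirical.csv")
  msg("fertility", "fitting ASFR model")
  asfr_fit <- fit_asfr_model(asfr_emp,
                             years = sort(unique(c(cfg$census_years, proj_years))),
                             settings = mc("fertility", 5000))
  asfr_med <- covariate_medians(asfr_fit)
  put_json(list(medians = asfr_med, parameters = tidy(asfr_fit)),
           "asfr_posterior.json")

  # -- survival ---------------------------------------------------------
  msg("survival", "interpolating life table")
  surv_years <- seq(min(cfg$census_years), max(proj_years))
  surv <- interpolate_survival(lifetable, ages = cfg$ages, years = surv_years,
                               mode = config$survival_mode %||% "direct")
  put_csv(surv, "survival_surface.csv")

  # -- population model -------------------------------------------------
  msg("population", "assembling frame and fitting")
  counts <- census_mwra_counts(census, cfg$register, ages = cfg$ages)
  frame <- build_frame(
    counts,
    dplyr::filter(netmig_med, .data$year %in% cfg$census_years),
    dplyr::filter(asfr_med, .data$year %in% cfg$census_years),
    surv, cfg$register)
  put_csv(frame, "model_frame.csv")
  pop_fit <- fit_population_model(frame, settings = mc("population", 10000))
  put_json(list(parameters = tidy(pop_fit), glance = glance(pop_fit)),
           "population_posterior.json")

  # -- projection (step two): driver posteriors paired draw-wise --------
  msg("project", "projecting %d-%d", min(proj_years), max(proj_years))
  newdata <- tidyr::expand_grid(division = cfg$register$division,
                                age = cfg$ages, year = proj_years) |>
    dplyr::left_join(cfg$register, by = "division") |>
    dplyr::left_join(dplyr::select(surv, "age", "year", X3 = "px1"),
                     by = c("age", "year"))
  proj <- project_population(
    pop_fit, newdata,
    x1_draws = covariate_draws(netmig_fit, newdata),
    x2_draws = covariate_draws(asfr_fit, newdata),
    seed = stage_seed(50L))

  # -- summaries --------------------------------------------------------
  msg("summarize", "tables and rates")
  table <- summarize_projection(proj)
  put_csv(table, "projections.csv")
  periods <- config$rate_periods %||% list(c(2000, 2030), c(2020, 2030))
  rates <- dplyr::bind_rows(lapply(periods, function(p) {
    dplyr::bind_rows(annual_rate(proj, p[1], p[2], level = "region"),
                     annual_rate(proj, p[1], p[2], level = "national"))
  }))
  put_csv(rates, "rates.csv")

  # -- diagnostics ------------------------------------------------------
  msg("diagnose", "convergence and posterior predictive checks")
  ppp <- ppp_check(pop_fit, seed = stage_seed(60L))
  diagnostics <- list(netmig = glance(netmig_fit), fertility = glance(asfr_fit),
                      population = glance(pop_fit), ppp = ppp)
  put_json(diagnostics, "diagnostics.json")

  # -- sensitivity ------------------------------------------------------
  sens_cfg <- config$sensitivity %||% list(enabled = FALSE)
  sens <- NULL
  if (isTRUE(sens_cfg$enabled)) {
    msg("sensitivity", "predictor exclusion and prior rescaling")
    sens <- run_sensitivity(
      frame, settings = mc("population", 10000),
      prior_scale_factors = sens_cfg$prior_scale_factors %||% 10,
      drop_sets = sens_cfg$drop_sets %||% list("X1", "X2X3"))
    put_json(sens, "sensitivity.json")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mwrapop")),
    seed = seed,
    stage_seeds = list(world = wargs$seed, netmig = mc("netmig", 10000)$seed,
                       fertility = mc("fertility", 5000)$seed,
                       population = mc("population", 10000)$seed,
                       projection = stage_seed(50L)),
    config = config[setdiff(names(config), "out_dir")],
    files = lapply(files, function(p) list(
      path = basename(p), md5 = unname(tools::md5sum(p)))),
    diagnostics = list(population_max_rhat = max(pop_fit$diagnostics$rhat, na.rm = TRUE),
                       population_converged = pop_fit$converged)
  )
  put_json(manifest, "manifest.json")
  msg("done", "artifacts in %s", config$out_dir)

  invisible(list(config = cfg, truth = truth, census = census, births = births,
                 lifetable = lifetable, migration_series = mig_series,
                 netmig_fit = netmig_fit, asfr_empirical = asfr_emp,
                 asfr_fit = asfr_fit, survival_surface = surv, frame = frame,
                 pop_fit = pop_fit, projection = proj, table = table,
                 rates = rates, diagnostics = diagnostics, sensitivity = sens,
                 manifest = manifest))
}
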