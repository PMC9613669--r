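# small deterministic MCMC settings for fast test fits
tiny_settings <- function(seed = 1, n_draws = 900, burn_in = 400, ...) {
  mcmc_settings(n_draws = n_draws, burn_in = burn_in, n_chains = 2,
                seed = seed, ...)
}

# reduced-scale recovery world: ages on the rising flank of the fertility
# schedule so the fertility-x-survival covariate varies across cells
recovery_config <- function(seed, ...) {
  world_config(seed = seed, n_regions = 2, divisions_per_region = 3,
               ages = 20:24, ...)
}

# frame built from truth covariates and census-sampled counts
recovery_frame <- function(cfg, truth) {
  census <- generate_census(cfg, truth)
  build_frame(census_mwra_counts(census, cfg$register, ages = cfg$ages),
              truth_migration_series(truth),
              truth_asfr_surface(truth),
              truth_survival_surface(truth),
              cfg$register)
}

# random toy census records for flow tests
toy_census <- function(n, register, seed, p_missing = 0.05) {
  withr::with_seed(seed, {
    div <- register$division
    tibble::tibble(
      census_year = 2005L,
      age = sample(15:49, n, replace = TRUE),
      sex = sample(c("female", "male"), n, replace = TRUE, prob = c(0.8, 0.2)),
      marital_status = sample(c("married", "other"), n, replace = TRUE),
      division_current = sample(div, n, replace = TRUE),
      division_previous = ifelse(runif(n) < p_missing, NA_character_,
                                 sample(div, n, replace = TRUE)),
      person_weight = sample(c(5, 10, 20), n, replace = TRUE)
    )
  })
}

published_medians <- function() {
  readr::read_csv(system.file("extdata", "table1_published_medians.csv",
                              package = "mwrapop"),
                  show_col_types = FALSE)
}
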