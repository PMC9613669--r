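#' Configuration for a synthetic study world
#'
#' Defines a small country with known demographic ground truth: divisions
#' nested in regions, census-style microdata with current and previous
#' division of residence, DHS-style retrospective birth histories, and an
#' abridged life table. Every downstream stage of the pipeline (migration,
#' fertility, survival, population model, summaries) accepts the generated
#' tables directly, so the whole method is testable without restricted
#' microdata.
#'
#' @param n_regions,divisions_per_region Size of the administrative register.
#' @param census_years Calendar years of the simulated censuses.
#' @param ages Integer ages of the reproductive span (a contiguous range
#'   within 15-49; the full span by default).
#' @param base_population_scale Expected married women per (age, division)
#'   cell at neutral covariates; sets the default intercept
#'   `beta0 = log(base_population_scale)`.
#' @param true_betas Named vector `c(beta0, beta1, beta2)`: intercept,
#'   net-migration effect, fertility-x-survival interaction effect of the
#'   ground-truth log-linear model.
#' @param migration_intensity Probability that a person reports a previous
#'   division different from the current one.
#' @param asfr_peak Ground-truth age-specific fertility rate (births per
#'   woman-year) at the modal age (27).
#' @param survival_level Ground-truth five-year survival probability 5px at
#'   age group 15-19 in the first period.
#' @param noise_sd Standard deviation of the log-scale random effects
#'   (u1 by age-division-year, u2 by division-year) in the ground truth.
#' @param seed Integer seed; fully determines all generated tables.
#' @param sample_weight Person weight of the census microdata (10 mirrors a
#'   10 percent sample).
#' @param n_women Number of women with birth histories per generated survey.
#' @param observation_model `"poisson"` (default) or `"lognormal"` noise for
#'   census cell counts around the ground-truth expectation.
#' @param prop_missing_previous Fraction of census rows with missing
#'   previous division of residence.
#' @param marriage_midpoint,marriage_scale Logistic-in-age proportion
#'   currently married: `plogis((age - midpoint) / scale)`.
#' @param all_women_factor All-women factor attached to generated birth
#'   histories.
#' @return An object of class `mwra_world_config`.
#' @examples
#' cfg <- world_config(seed = 7)
#' truth <- ground_truth(cfg)
#' head(truth$cells)
#' @export
world_config <- function(n_regions = 2, divisions_per_region = 2,
                         census_years = c(1976, 1987, 2005),
                         ages = 15:49,
                         base_population_scale = 400,
                         true_betas = NULL,
                         migration_intensity = 0.05,
                         asfr_peak = 0.22,
                         survival_level = 0.98,
                         noise_sd = 0.05,
                         seed = 1L,
                         sample_weight = 10,
                         n_women = 2000,
                         observation_model = c("poisson", "lognormal"),
                         prop_missing_previous = 0.02,
                         marriage_midpoint = 20,
                         marriage_scale = 4,
                         all_women_factor = 1) {
  n_regions <- assert_count(n_regions, "n_regions")
  divisions_per_region <- assert_count(divisions_per_region, "divisions_per_region")
  if (length(census_years) < 2 || is.unsorted(census_years)) {
    config_error("census_years", "need >= 2 increasing calendar years")
  }
  ages <- sort(unique(as.integer(ages)))
  if (!all(diff(ages) == 1) || min(ages) < 15 || max(ages) > 49) {
    config_error("ages", "must be a contiguous integer range within 15..49")
  }
  if (!is.numeric(base_population_scale) || base_population_scale <= 0) {
    config_error("base_population_scale", "must be > 0")
  }
  if (is.null(true_betas)) {
    true_betas <- c(beta0 = log(base_population_scale), beta1 = 1, beta2 = 1.5)
  }
  if (length(true_betas) != 3) config_error("true_betas", "need (beta0, beta1, beta2)")
  names(true_betas) <- c("beta0", "beta1", "beta2")
  if (!is.numeric(migration_intensity) || migration_intensity < 0 || migration_intensity > 1) {
    config_error("migration_intensity", "must lie in [0, 1]")
  }
  assert_prob(asfr_peak, "asfr_peak")
  assert_prob(survival_level, "survival_level")
  if (!is.numeric(noise_sd) || noise_sd < 0) config_error("noise_sd", "must be >= 0")
  if (!is.numeric(sample_weight) || sample_weight <= 0) {
    config_error("sample_weight", "must be > 0")
  }
  n_women <- assert_count(n_women, "n_women")
  structure(list(
    n_regions = n_regions, divisions_per_region = divisions_per_region,
    census_years = as.integer(census_years), ages = ages,
    base_population_scale = base_population_scale, true_betas = true_betas,
    migration_intensity = migration_intensity, asfr_peak = asfr_peak,
    survival_level = survival_level, noise_sd = noise_sd,
    seed = as.integer(seed), sample_weight = sample_weight,
    n_women = n_women, observation_model = match.arg(observation_model),
    prop_missing_previous = prop_missing_previous,
    marriage_midpoint = marriage_midpoint, marriage_scale = marriage_scale,
    all_women_factor = all_women_factor,
    register = admin_register(n_regions, divisions_per_region)
  ), class = "mwra_world_config")
}

#' Ground truth of a synthetic world
#'
#' Evaluates the true expected married-women population per (age, division,
#' region, year) as an exact log-linear identity:
#' `log(eta_star) = beta0 + beta1 * X1 + beta2 * X2 * X3 + u1 + u2`,
#' where X1 is the age proportion of net-migration, X2 the age-specific
#' fertility rate, X3 the single-age survival probability, and u1, u2 are
#' zero-mean normal random effects drawn once per world.
#'
#' @param config A [world_config()].
#' @param years Calendar years to evaluate; defaults to the census years
#'   plus the projection span 2000-2030.
#' @return An object of class `mwra_ground_truth` with elements `cells`
#'   (tibble of truths per cell), `betas`, `register`, and `config`.
#' @export
ground_truth <- function(config, years = NULL) {
  stopifnot(inherits(config, "mwra_world_config"))
  years <- sort(unique(as.integer(years %||% c(config$census_years, 2000:2030))))
  reg <- config$register
  cells <- tidyr::expand_grid(
    division = reg$division, age = config$ages, year = years
  ) |>
    dplyr::left_join(reg, by = "division")

  d_idx <- match(cells$division, reg$division)
  r_idx <- match(cells$region, unique(reg$region))

  # X1: hump-shaped age profile of net-migration proportions, mode shifted
  # slightly by division, normalised to sum to 1 over ages within division
  mode1 <- 22 + (d_idx %% 3) - 1
  w1 <- exp(-(cells$age - mode1)^2 / (2 * 4^2))
  tot1 <- stats::ave(w1, cells$division, cells$year, FUN = sum)
  cells$X1 <- w1 / tot1

  # X2: fertility schedule peaking at age 27, region level shift, slow
  # secular decline
  rmult <- 1 + 0.08 * (r_idx - (config$n_regions + 1) / 2)
  cells$X2 <- pmin(1, config$asfr_peak * exp(-(cells$age - 27)^2 / (2 * 6^2)) *
                     rmult * exp(-0.004 * (cells$year - 2000)))

  # X3: national single-age survival, declining in age, improving in time
  cells$X3 <- pmin(1 - 1e-9,
                   config$survival_level - 8e-4 * (cells$age - 15) +
                     2e-4 * (cells$year - min(years)))

  cells <- with_seed(derive_seed(config$seed, 100L), {
    u2_keys <- dplyr::distinct(cells, .data$division, .data$year)
    u2_keys$u2 <- rnorm(nrow(u2_keys), 0, config$noise_sd)
    cells$u1 <- rnorm(nrow(cells), 0, config$noise_sd)
    dplyr::left_join(cells, u2_keys, by = c("division", "year"))
  })

  b <- config$true_betas
  cells$log_eta_star <- b[["beta0"]] + b[["beta1"]] * cells$X1 +
    b[["beta2"]] * cells$X2 * cells$X3 + cells$u1 + cells$u2
  cells$eta_star <- exp(cells$log_eta_star)

  structure(list(cells = cells[, c("age", "division", "region", "year",
                                   "X1", "X2", "X3", "u1", "u2",
                                   "log_eta_star", "eta_star")],
                 betas = b, register = reg, config = config),
            class = "mwra_ground_truth")
}

#' @export
print.mwra_ground_truth <- function(x, ...) {
  cat(sprintf("<mwra_ground_truth> %d cells; betas: %s\n", nrow(x$cells),
              paste(sprintf("%s=%.3g", names(x$betas), x$betas), collapse = ", ")))
  invisible(x)
}

#' Covariate surfaces stored in the ground truth
#'
#' Accessors returning the true net-migration age-proportion series, the
#' true regional fertility surface, and the true national survival surface
#' in the schemas expected by the downstream modules (useful for
#' round-trip tests and truth-covariate projections).
#'
#' @param truth A [ground_truth()] object.
#' @return A tibble in the respective module's input schema.
#' @export
truth_migration_series <- function(truth) {
  dplyr::distinct(truth$cells, .data$age, .data$division, .data$year, X1 = .data$X1)
}

#' @rdname truth_migration_series
#' @export
truth_asfr_surface <- function(truth) {
  dplyr::distinct(truth$cells, .data$age, .data$region, .data$year, asfr = .data$X2)
}

#' @rdname truth_migration_series
#' @export
truth_survival_surface <- function(truth) {
  dplyr::distinct(truth$cells, .data$age, .data$year, px1 = .data$X3)
}

#' Generate census-style person microdata
#'
#' One row per sampled person with current and previous division of
#' residence, single age, sex, marital status and a person weight (a
#' `sample_weight = 10` world mirrors 10 percent sample microdata).
#' Weighted married-women counts per (age, division, year) are unbiased for
#' the ground-truth expectation: the number of sampled married women in a
#' cell is Poisson with mean `eta_star / sample_weight` (or log-normal when
#' `observation_model = "lognormal"`). Unmarried women are added through a
#' logistic-in-age proportion married, and men through a matching male
#' population, so downstream subsetting to married women of reproductive
#' age is exercised. Movers receive a previous division different from the
#' current one with probability `migration_intensity`.
#'
#' @param config A [world_config()].
#' @param truth The matching [ground_truth()].
#' @param years Census years to generate (default: all in the config).
#' @return A tibble of person records with columns `census_year`, `age`,
#'   `sex`, `marital_status`, `division_current`, `division_previous`,
#'   `person_weight`.
#' @export
generate_census <- function(config, truth, years = config$census_years) {
  stopifnot(inherits(config, "mwra_world_config"),
            inherits(truth, "mwra_ground_truth"))
  missing_years <- setdiff(years, unique(truth$cells$year))
  if (length(missing_years)) {
    config_error("census_years", paste("ground truth does not cover year(s)",
                                       paste(missing_years, collapse = ", ")))
  }
  w <- config$sample_weight
  cells <- dplyr::filter(truth$cells, .data$year %in% years)
  p_married <- stats::plogis((cells$age - config$marriage_midpoint) / config$marriage_scale)

  with_seed(derive_seed(config$seed, 200L), {
    lambda_married <- if (config$observation_model == "poisson") {
      cells$eta_star / w
    } else {
      exp(log(cells$eta_star) + rnorm(nrow(cells), 0, config$noise_sd)) / w
    }
    n_mar <- rpois(nrow(cells), lambda_married)
    n_unm <- rpois(nrow(cells), lambda_married * (1 - p_married) / p_married)
    n_men <- rpois(nrow(cells), lambda_married / p_married)

    counts <- tibble::tibble(
      census_year = rep(cells$year, 3L),
      age = rep(cells$age, 3L),
      division_current = rep(cells$division, 3L),
      sex = rep(c("female", "female", "male"), each = nrow(cells)),
      marital_status = rep(c("married", "other", "other"), each = nrow(cells)),
      n = c(n_mar, n_unm, n_men)
    )
    persons <- tidyr::uncount(counts, weights = .data$n)
    persons$person_weight <- w

    divisions <- config$register$division
    n_div <- length(divisions)
    moved <- runif(nrow(persons)) < config$migration_intensity
    prev <- persons$division_current
    if (n_div > 1 && any(moved)) {
      # uniform among the other divisions
      shift <- sample.int(n_div - 1, sum(moved), replace = TRUE)
      cur_i <- match(prev[moved], divisions)
      prev[moved] <- divisions[((cur_i - 1 + shift) %% n_div) + 1]
    }
    prev[runif(nrow(persons)) < config$prop_missing_previous] <- NA_character_
    persons$division_previous <- prev
    persons[, c("census_year", "age", "sex", "marital_status",
                "division_current", "division_previous", "person_weight")]
  })
}

#' Generate DHS-style retrospective birth histories
#'
#' Simulates one row per interviewed woman: interview date and her own
#' birth date in century-month codes (CMC), sampling weight, all-women
#' factor, region, and the CMC of each live birth. Births arise from a
#' piecewise-constant monthly hazard equal to the supplied true
#' age-specific fertility rate at the woman's completed age and calendar
#' year, divided by 12.
#'
#' @param config A [world_config()].
#' @param truth_asfr True fertility surface: tibble with columns `age`,
#'   `region`, `year`, `asfr` (births per woman-year, each in \[0, 1\]).
#' @param n_women Number of women to simulate (split evenly over regions).
#' @param survey_year Calendar year of the interview.
#' @return A tibble with columns `woman_id`, `region`, `woman_birth_cmc`,
#'   `interview_cmc`, `weight`, `all_women_factor`, and the list-column
#'   `child_birth_cmcs`.
#' @export
generate_birth_histories <- function(config, truth_asfr,
                                     n_women = config$n_women,
                                     survey_year = max(config$census_years)) {
  stopifnot(inherits(config, "mwra_world_config"))
  if (!all(c("age", "region", "year", "asfr") %in% names(truth_asfr))) {
    rlang::abort("truth_asfr needs columns age, region, year, asfr")
  }
  if (any(!is.finite(truth_asfr$asfr)) || any(truth_asfr$asfr < 0) ||
      any(truth_asfr$asfr > 1)) {
    rlang::abort("fertility rates must lie in [0, 1] per woman-year",
                 class = "mwrapop_validation_error")
  }
  regions <- sort(unique(truth_asfr$region))
  ages_t <- sort(unique(truth_asfr$age))
  years_t <- sort(unique(truth_asfr$year))
  # dense lookup array: hazard per month, clamped to the covered grid
  rate <- array(0, dim = c(length(ages_t), length(regions), length(years_t)))
  rate[cbind(match(truth_asfr$age, ages_t), match(truth_asfr$region, regions),
             match(truth_asfr$year, years_t))] <- truth_asfr$asfr

  with_seed(derive_seed(config$seed, 300L), {
    region <- rep(regions, length.out = n_women)
    age_at_interview <- runif(n_women, 15, 50)
    interview_cmc <- cmc(survey_year, sample.int(12, n_women, replace = TRUE))
    woman_birth_cmc <- as.integer(interview_cmc - round(age_at_interview * 12))

    start <- woman_birth_cmc + 180L                     # month of 15th birthday
    end <- pmin(interview_cmc - 1L, woman_birth_cmc + 599L)  # last month before 50/interview
    n_m <- pmax(0L, end - start + 1L)
    wid <- rep(seq_len(n_women), n_m)
    m <- unlist(lapply(seq_len(n_women), function(i) {
      if (n_m[i] > 0) seq.int(start[i], end[i]) else integer(0)
    }), use.names = FALSE)

    a_i <- pmin(pmax(cmc_age(m, woman_birth_cmc[wid]), min(ages_t)), max(ages_t))
    y_i <- pmin(pmax(cmc_year(m), min(years_t)), max(years_t))
    hz <- rate[cbind(match(a_i, ages_t), match(region[wid], regions),
                     match(y_i, years_t))] / 12
    birth <- runif(length(m)) < hz

    births_by_woman <- split(m[birth], factor(wid[birth], levels = seq_len(n_women)))
    tibble::tibble(
      woman_id = seq_len(n_women),
      region = region,
      woman_birth_cmc = woman_birth_cmc,
      interview_cmc = interview_cmc,
      weight = 1,
      all_women_factor = rep(config$all_women_factor, length.out = n_women),
      child_birth_cmcs = unname(births_by_woman)
    )
  })
}

#' Generate an abridged life table
#'
#' Five-year female survival probabilities `px5` (probability of surviving
#' from exact age x to x+5) by 5-year age group (15-19 ... 45-49) and
#' 5-year calendar period covering 1976-2030. The schedule declines with
#' age within every period and improves slowly over time, so values are
#' always in (0, 1] and monotone non-increasing in age.
#'
#' @param config A [world_config()].
#' @return A tibble with columns `period_start_year`, `age_group_start`,
#'   `px5`.
#' @export
generate_life_tables <- function(config) {
  stopifnot(inherits(config, "mwra_world_config"))
  assert_prob(config$survival_level, "survival_level")
  grid <- tidyr::expand_grid(period_start_year = seq(1975L, 2025L, by = 5L),
                             age_group_start = seq(15L, 45L, by = 5L))
  g <- (grid$age_group_start - 15L) / 5L
  p <- (grid$period_start_year - 1975L) / 5L
  grid$px5 <- pmin(1, pmax(1e-6, config$survival_level - 0.004 * g + 5e-4 * p))
  grid
}

#' Simulate a complete synthetic world
#'
#' Convenience wrapper running all three generators against one ground
#' truth.
#'
#' @param config A [world_config()].
#' @return A list with elements `truth`, `census`, `births`, `lifetable`.
#' @export
simulate_world <- function(config) {
  truth <- ground_truth(config)
  list(truth = truth,
       census = generate_census(config, truth),
       births = generate_birth_histories(config, truth_asfr_surface(truth)),
       lifetable = generate_life_tables(config))
}
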