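test_that("the frame round-trips the generator's stored covariates exactly", {
  cfg <- recovery_config(seed = 71)
  truth <- ground_truth(cfg, years = cfg$census_years)
  counts <- dplyr::transmute(truth$cells, year, division, age,
                             count = round(eta_star))
  frame <- build_frame(counts, truth_migration_series(truth),
                       truth_asfr_surface(truth),
                       truth_survival_surface(truth), cfg$register)
  joined <- dplyr::inner_join(
    frame, truth$cells, by = c("age", "division", "region", "year"),
    suffix = c("", ".t"))
  expect_equal(nrow(joined), nrow(frame))
  expect_identical(joined$X1, joined$X1.t)
  expect_identical(joined$X2, joined$X2.t)
  expect_identical(joined$X3, joined$X3.t)
  expect_identical(frame$X2X3, frame$X2 * frame$X3)
  cors <- attr(frame, "covariate_correlations")
  expect_false(any(cors$constant))
})

test_that("a division missing from the fertility surface raises a coverage error", {
  cfg <- recovery_config(seed = 72)
  truth <- ground_truth(cfg, years = cfg$census_years)
  counts <- dplyr::transmute(truth$cells, year, division, age,
                             count = round(eta_star))
  dropped_region <- cfg$register$region[1]
  dropped_division <- cfg$register$division[1]
  asfr <- dplyr::filter(truth_asfr_surface(truth), region != dropped_region)
  err <- expect_error(
    build_frame(counts, truth_migration_series(truth), asfr,
                truth_survival_surface(truth), cfg$register),
    class = "mwrapop_coverage_error")
  expect_match(conditionMessage(err), dropped_division, fixed = TRUE)
})

test_that("constant covariates are flagged in the correlation diagnostic", {
  cfg <- recovery_config(seed = 73)
  truth <- ground_truth(cfg, years = cfg$census_years)
  counts <- dplyr::transmute(truth$cells, year, division, age,
                             count = round(eta_star))
  surv_const <- dplyr::mutate(truth_survival_surface(truth), px1 = 0.98)
  frame <- build_frame(counts, truth_migration_series(truth),
                       truth_asfr_surface(truth), surv_const, cfg$register)
  cors <- attr(frame, "covariate_correlations")
  expect_true(cors$constant[cors$pair == "X1~X3"])
  expect_true(is.na(cors$r[cors$pair == "X2~X3"]))
})

test_that("zero counts are offset before logging, with a warning", {
  cfg <- recovery_config(seed = 74)
  truth <- ground_truth(cfg, years = cfg$census_years)
  counts <- dplyr::transmute(truth$cells, year, division, age,
                             count = round(eta_star))
  counts$count[1] <- 0
  expect_warning(
    frame <- build_frame(counts, truth_migration_series(truth),
                         truth_asfr_surface(truth),
                         truth_survival_surface(truth), cfg$register),
    "offset")
  expect_true(frame$log_offset[1])
  expect_equal(frame$log_count[1], log(0.5))
})

test_that("stored draws satisfy the linear-predictor identity exactly", {
  cfg <- recovery_config(seed = 75)
  truth <- ground_truth(cfg, years = cfg$census_years)
  frame <- recovery_frame(cfg, truth)
  fit <- suppressWarnings(fit_population_model(frame, tiny_settings(seed = 1,
                                                                    n_draws = 500,
                                                                    burn_in = 200)))
  m <- draws_matrix(fit$draws)
  j1 <- match(paste(frame$age, frame$division, frame$year),
              paste(fit$u1_keys$age, fit$u1_keys$division, fit$u1_keys$year))
  j2 <- match(paste(frame$division, frame$year),
              paste(fit$u2_keys$division, fit$u2_keys$year))
  mu_rebuilt <- m[, "beta0"] + outer(m[, "beta1"], frame$X1) +
    outer(m[, "beta2"], frame$X2X3) +
    m[, sprintf("u1[%d]", j1), drop = FALSE] +
    m[, sprintf("u2[%d]", j2), drop = FALSE]
  mu_stored <- m[, sprintf("mu[%d]", seq_len(nrow(frame))), drop = FALSE]
  expect_lt(max(abs(mu_rebuilt - mu_stored)), 1e-8)
})

test_that("with no covariate effects and no noise, predictions collapse to the intercept", {
  cfg <- recovery_config(seed = 76)
  truth <- ground_truth(cfg, years = cfg$census_years)
  frame <- build_frame(
    dplyr::transmute(truth$cells, year, division, age, count = exp(5)),
    truth_migration_series(truth), truth_asfr_surface(truth),
    truth_survival_surface(truth), cfg$register)
  fit <- suppressWarnings(fit_population_model(frame, tiny_settings(seed = 2,
                                                                    n_draws = 1200,
                                                                    burn_in = 500)))
  mu <- draws_matrix(fit$draws)[, sprintf("mu[%d]", seq_len(nrow(frame)))]
  expect_true(all(abs(apply(mu, 2, median) - 5) <= 0.01))
})

test_that("doubling the fertility-survival product shifts predictions by beta2 exactly", {
  cfg <- recovery_config(seed = 77)
  truth <- ground_truth(cfg, years = c(cfg$census_years, 2030))
  frame <- recovery_frame(cfg, truth)
  fit <- suppressWarnings(fit_population_model(frame, tiny_settings(seed = 3,
                                                                    n_draws = 500,
                                                                    burn_in = 200)))
  nd <- dplyr::select(dplyr::filter(truth$cells, year == 2030),
                      age, division, region, year, X1, X2, X3)
  p1 <- project_population(fit, nd, seed = 5)
  p2 <- project_population(fit, dplyr::mutate(nd, X2 = 2 * X2), seed = 5)
  shift <- log(p2$counts) - log(p1$counts)
  beta2 <- draws_matrix(fit$draws)[, "beta2"]
  expected <- outer(beta2, nd$X2 * nd$X3)
  expect_lt(max(abs(shift - expected)), 1e-10)
})

test_that("projections with frozen covariates and no noise are constant over years", {
  cfg <- recovery_config(seed = 78)
  truth <- ground_truth(cfg, years = cfg$census_years)
  frame <- recovery_frame(cfg, truth)
  fit <- suppressWarnings(fit_population_model(frame, tiny_settings(seed = 4,
                                                                    n_draws = 500,
                                                                    burn_in = 200)))
  last <- dplyr::filter(truth$cells, year == max(cfg$census_years))
  nd <- tidyr::expand_grid(year = 2000:2003,
                           dplyr::select(last, age, division, region, X1, X2, X3))
  proj <- project_population(fit, nd, include_u = FALSE,
                             include_residual = FALSE, seed = 6)
  by_year <- split(seq_len(nrow(nd)), nd$year)
  for (k in seq_along(by_year)[-1]) {
    expect_identical(proj$counts[, by_year[[1]]], proj$counts[, by_year[[k]]])
  }
})

test_that("the sampler is reproducible and seed-stable", {
  cfg <- recovery_config(seed = 79)
  truth <- ground_truth(cfg, years = cfg$census_years)
  frame <- recovery_frame(cfg, truth)
  f1 <- suppressWarnings(fit_population_model(frame, tiny_settings(seed = 11,
                                                                   n_draws = 700,
                                                                   burn_in = 300)))
  f2 <- suppressWarnings(fit_population_model(frame, tiny_settings(seed = 11,
                                                                   n_draws = 700,
                                                                   burn_in = 300)))
  expect_identical(draws_matrix(f1$draws), draws_matrix(f2$draws))

  f3 <- suppressWarnings(fit_population_model(frame, tiny_settings(seed = 12,
                                                                   n_draws = 700,
                                                                   burn_in = 300)))
  for (p in c("beta0", "beta1", "beta2")) {
    d1 <- draws_matrix(f1$draws)[, p]
    d3 <- draws_matrix(f3$draws)[, p]
    expect_lt(abs(median(d1) - median(d3)), 0.5 * sd(d1))
  }
})

test_that("with the outcome removed the sampler reproduces the prior", {
  cfg <- recovery_config(seed = 80)
  truth <- ground_truth(cfg, years = cfg$census_years)
  frame <- recovery_frame(cfg, truth)
  fit <- suppressWarnings(
    fit_population_model(frame, tiny_settings(seed = 13, n_draws = 4200,
                                              burn_in = 200),
                         prior_only = TRUE))
  b0 <- draws_matrix(fit$draws)[, "beta0"]
  expect_lt(abs(mean(b0)), 1)          # prior mean 0, sd 10
  expect_equal(sd(b0), 10, tolerance = 0.15)
  s2 <- draws_matrix(fit$draws)[, "sigma_u2"]
  # half-normal(1): median 0.674
  expect_equal(median(s2), stats::qnorm(0.75), tolerance = 0.15)
})

test_that("degenerate frames and missing covariates are rejected", {
  cfg <- recovery_config(seed = 81)
  truth <- ground_truth(cfg, years = cfg$census_years)
  frame <- recovery_frame(cfg, truth)
  expect_error(fit_population_model(frame[1, ], tiny_settings()),
               class = "mwrapop_validation_error")
  one_year <- dplyr::filter(frame, year == min(year))
  expect_error(fit_population_model(one_year, tiny_settings()),
               class = "mwrapop_validation_error")

  fit <- suppressWarnings(fit_population_model(frame, tiny_settings(seed = 1,
                                                                    n_draws = 400,
                                                                    burn_in = 200)))
  nd <- dplyr::select(dplyr::filter(truth$cells, year == 2005),
                      age, division, region, year, X1, X2)
  expect_error(project_population(fit, nd), class = "mwrapop_coverage_error")
})
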