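# hand-built projection-draws object
fake_proj <- function(counts, cells) {
  structure(list(counts = counts, cells = cells,
                 chain = rep(1:2, each = nrow(counts) / 2)),
            class = "mwra_projection_draws")
}

# hand-built population fit exposing mu and sigma_obs draws
fake_fit <- function(mu, sigma, frame) {
  colnames(mu) <- sprintf("mu[%d]", seq_len(ncol(mu)))
  m <- cbind(mu, sigma_obs = sigma)
  draws <- structure(list(draws = m, chain = rep(1:2, each = nrow(m) / 2),
                          settings = NULL), class = "mwra_draws")
  structure(list(draws = draws, frame = frame,
                 priors = pop_priors(), diagnostics = NULL),
            class = c("mwra_pop_fit", "mwra_fit"))
}

test_that("constant draws summarise to 35 x the constant with a degenerate interval", {
  cells <- tidyr::expand_grid(age = 15:49, division = "d1", region = "R01",
                              year = 2030)
  proj <- fake_proj(matrix(7, nrow = 50, ncol = 35), cells)
  tab <- summarize_projection(proj)
  nat <- tab[tab$level == "national", ]
  expect_equal(nat$count_median, 35 * 7)
  expect_equal(nat$median_of_sums, 35 * 7)
  expect_equal(nat$cri_low, 35 * 7)
  expect_equal(nat$cri_high, 35 * 7)
})

test_that("percentiles follow the linear-interpolation rule, against a sort-based oracle", {
  x <- c(1, 2, 3, 4, 100)
  # type-7 oracle: h = (n - 1) p + 1 interpolated between order statistics
  oracle <- function(x, p) {
    s <- sort(x); h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[pmin(lo + 1, length(x))] - s[lo])
  }
  cells <- tibble::tibble(age = 20, division = "d1", region = "R01", year = 2030)
  proj <- fake_proj(matrix(rep(x, 2), ncol = 1), cells)
  tab <- summarize_projection(proj, levels = "division")
  expect_equal(tab$median_of_sums, 3)
  expect_equal(tab$cri_low, oracle(rep(x, 2), 0.025))
  expect_equal(tab$cri_high, oracle(rep(x, 2), 0.975))

  withr::with_seed(4, {
    big <- rlnorm(5000)
    proj2 <- fake_proj(matrix(big, ncol = 1), cells)
    tab2 <- summarize_projection(proj2, levels = "division")
    expect_equal(tab2$cri_low, oracle(big, 0.025))
    expect_equal(tab2$cri_high, oracle(big, 0.975))
  })
})

test_that("sum-of-medians and median-of-sums diverge on skewed draws and agree on symmetric ones", {
  cells <- tidyr::expand_grid(age = 15:24, division = "d1", region = "R01",
                              year = 2030)
  withr::with_seed(5, {
    skewed <- matrix(rlnorm(4000 * 10, 0, 1.5), 4000, 10)
    symm <- matrix(rnorm(4000 * 10, 100, 1), 4000, 10)
  })
  tab_s <- summarize_projection(fake_proj(skewed, cells), levels = "division")
  # independent right-skewed cells: the median of the sum exceeds the sum of
  # cell medians (each cell median sits below its mean)
  expect_gt(tab_s$median_of_sums, tab_s$count_median)
  tab_n <- summarize_projection(fake_proj(symm, cells), levels = "division")
  expect_equal(tab_n$median_of_sums, tab_n$count_median, tolerance = 1e-3)
  # symmetric draws: median tracks the mean
  expect_equal(tab_n$median_of_sums, 1000, tolerance = 1e-3)
})

test_that("annual rates reproduce published endpoint arithmetic and degenerate cases", {
  expect_equal(round(annual_rate_points(109582, 208402, 2000, 2030), 2), 3.01)
  expect_equal(annual_rate_points(100, 100, 2000, 2030), 0)
  expect_equal(annual_rate_points(50, 100, 2000, 2010), 10)
  expect_error(annual_rate_points(0, 10, 2000, 2010),
               class = "mwrapop_validation_error")
})

test_that("per-draw rates are summarised with credible intervals", {
  cells <- tidyr::expand_grid(age = 20, division = "d1", region = "R01",
                              year = c(2000, 2030))
  withr::with_seed(6, {
    p1 <- rlnorm(2000, log(100), 0.05)
    p2 <- rlnorm(2000, log(200), 0.05)
  })
  proj <- fake_proj(cbind(p1, p2), cells)
  r <- annual_rate(proj, 2000, 2030, level = "national")
  draws_r <- 100 * (p2 - p1) / (p1 * 30)
  expect_equal(r$rate_median, median(draws_r))
  expect_lt(r$rate_cri_low, r$rate_median)
  expect_gt(r$rate_cri_high, r$rate_median)
  expect_error(annual_rate(proj, 2000, 2020), class = "mwrapop_validation_error")
})

test_that("identical chains give R-hat of exactly one", {
  withr::with_seed(7, ch <- rnorm(2000))
  expect_identical(gelman_rubin(cbind(ch, ch)), 1)
})

test_that("stationary chains pass and separated chains fail the R-hat check", {
  withr::with_seed(8, {
    good <- cbind(rnorm(2000), rnorm(2000))
    bad <- cbind(rnorm(200, 0), rnorm(200, 10))
  })
  expect_lt(gelman_rubin(good), 1.05)
  expect_gt(gelman_rubin(bad), 1.1)
  expect_error(gelman_rubin(matrix(rnorm(100), ncol = 1)),
               class = "mwrapop_validation_error")
})

test_that("R-hat agrees with the coda diagnostic on stationary chains", {
  withr::with_seed(9, x <- cbind(rnorm(3000), rnorm(3000)))
  ours <- gelman_rubin(x)
  codas <- coda::gelman.diag(coda::mcmc.list(coda::mcmc(x[, 1]),
                                             coda::mcmc(x[, 2])),
                             autoburnin = FALSE)$psrf[[1, 1]]
  expect_equal(ours, codas, tolerance = 0.02)
})

test_that("effective sample size is near n for independent draws", {
  withr::with_seed(10, x <- cbind(rnorm(2000), rnorm(2000)))
  expect_equal(effective_draws(x), 4000, tolerance = 0.25)
})

test_that("posterior predictive p-values behave at the extremes and in the middle", {
  n_cells <- 30; S <- 2000
  withr::with_seed(11, {
    mu <- matrix(rnorm(S * n_cells, 5, 0.01), S, n_cells)
    y <- rnorm(n_cells, 5, 0.1)
    y <- y - mean(y) + 5  # centre the observed statistic on the replication mean
  })
  frame <- tibble::tibble(log_count = y)
  fit <- fake_fit(mu, sigma = rep(0.1, S), frame)
  mid <- ppp_check(fit, statistics = "mean", seed = 2)
  expect_gt(mid$ppp, 0.05 + 0.2); expect_lt(mid$ppp, 0.95 - 0.2)

  hi <- ppp_check(fit, observed = tibble::tibble(log_count = y + 10),
                  statistics = "mean", seed = 2)
  expect_equal(hi$ppp, 0)   # observed above every replicate
  lo <- ppp_check(fit, observed = tibble::tibble(log_count = y - 10),
                  statistics = "mean", seed = 2)
  expect_equal(lo$ppp, 1)   # observed below every replicate
})

test_that("predictor exclusion hurts more than prior rescaling when the signal is strong", {
  cfg <- recovery_config(seed = 91, true_betas = c(6, 1, 4), noise_sd = 0.03)
  truth <- ground_truth(cfg, years = cfg$census_years)
  frame <- recovery_frame(cfg, truth)
  sens <- suppressWarnings(run_sensitivity(
    frame, settings = tiny_settings(seed = 14, n_draws = 600, burn_in = 300),
    drop_sets = list("X2X3"), prior_scale_factors = 10))
  excl <- sens$median_pct_diff[sens$variant == "drop_X2X3"]
  prio <- sens$median_pct_diff[sens$variant == "priors_x10"]
  expect_true(all(excl > prio))
})
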