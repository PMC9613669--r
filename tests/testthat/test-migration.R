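make_record <- function(cur, prev, weight = 10, age = 25, year = 2005) {
  tibble::tibble(census_year = year, age = age, sex = "female",
                 marital_status = "married", division_current = cur,
                 division_previous = prev, person_weight = weight)
}

test_that("a single mover is counted in both directions", {
  reg <- admin_register(1, 2)
  a <- reg$division[1]; b <- reg$division[2]
  rec <- make_record(a, b)  # moved b -> a
  flows <- compute_flows(rec, reg)
  net <- tapply(flows$net_count, flows$division, sum)
  expect_equal(unname(net[a]), 10)
  expect_equal(unname(net[b]), -10)
  expect_equal(sum(flows$net_count), 0)
})

test_that("stayers and missing previous residence produce no flows", {
  reg <- admin_register(1, 2)
  a <- reg$division[1]
  rec <- dplyr::bind_rows(make_record(a, a), make_record(a, NA))
  flows <- compute_flows(rec, reg)
  expect_true(all(flows$in_count == 0))
  expect_true(all(flows$out_count == 0))
  expect_true(all(flows$net_count == 0))
})

test_that("flow computation matches a brute-force oracle on a random toy census", {
  reg <- admin_register(2, 2)
  rec <- toy_census(500, reg, seed = 77)
  flows <- compute_flows(rec, reg)

  # oracle: loop over every ordered division pair and sum weights directly
  mwra <- rec[rec$sex == "female" & rec$marital_status == "married" &
                rec$age >= 15 & rec$age <= 49, ]
  for (d in reg$division) {
    for (a in 15:49) {
      sub <- mwra[mwra$age == a, ]
      in_d <- out_d <- 0
      for (o in reg$division) {
        if (o == d) next
        in_d <- in_d + sum(sub$person_weight[
          !is.na(sub$division_previous) & sub$division_current == d &
            sub$division_previous == o])
        out_d <- out_d + sum(sub$person_weight[
          !is.na(sub$division_previous) & sub$division_previous == d &
            sub$division_current == o])
      }
      row <- flows[flows$division == d & flows$age == a, ]
      expect_equal(row$in_count, in_d)
      expect_equal(row$out_count, out_d)
      expect_equal(row$net_count, in_d - out_d)
    }
  }
  # closed system and hierarchical consistency
  expect_equal(sum(flows$net_count), 0)
  div_tot <- tapply(flows$net_count, flows$division, sum)
  reg_tot <- tapply(flows$net_count, flows$region, sum)
  agg <- tapply(div_tot, reg$region[match(names(div_tot), reg$division)], sum)
  expect_equal(unname(agg[names(reg_tot)]), unname(reg_tot))
})

test_that("empty MWRA subsets warn and unknown divisions error", {
  reg <- admin_register(1, 2)
  men <- make_record(reg$division[1], reg$division[2])
  men$sex <- "male"
  expect_warning(flows <- compute_flows(men, reg), "no married women")
  expect_equal(nrow(flows), 0)
  bad <- make_record("nowhere", reg$division[1])
  expect_error(compute_flows(bad, reg), class = "mwrapop_registry_error")
})

test_that("boundary harmonization splits and conserves counts", {
  reg <- admin_register(1, 2)
  series <- tibble::tibble(census_year = 1976, division = "old1",
                           region = "R01", age = c(20, 21),
                           in_count = c(100, 40), out_count = c(0, 10),
                           net_count = c(100, 30))
  map <- tibble::tibble(old_division = "old1",
                        new_division = reg$division,
                        share = c(0.6, 0.4))
  out <- harmonize_flows(series, map)
  expect_equal(out$in_count[out$division == reg$division[1] & out$age == 20], 60)
  expect_equal(out$in_count[out$division == reg$division[2] & out$age == 20], 40)
  expect_equal(sum(out$net_count), sum(series$net_count))

  # identity map leaves a series unchanged
  id_map <- tibble::tibble(old_division = reg$division,
                           new_division = reg$division, share = 1)
  flows <- compute_flows(toy_census(300, reg, seed = 5), reg)
  same <- harmonize_flows(flows, id_map)
  joined <- dplyr::inner_join(flows, same, by = c("census_year", "division", "age"))
  expect_equal(joined$net_count.x, joined$net_count.y)

  # random valid map conserves grand totals to additive floating tolerance
  withr::with_seed(8, {
    big <- admin_register(2, 3)
    flows2 <- compute_flows(toy_census(800, big, seed = 9), big)
    raw <- matrix(runif(6 * 4), 6, 4)
    shares <- raw / rowSums(raw)
    rmap <- tibble::tibble(
      old_division = rep(big$division, each = 4),
      new_division = rep(big$division[1:4], times = 6),
      share = as.vector(t(shares)))
    out2 <- harmonize_flows(flows2, rmap)
    for (cc in c("in_count", "out_count", "net_count")) {
      expect_lt(abs(sum(out2[[cc]]) - sum(flows2[[cc]])),
                1e-9 * max(1, abs(sum(flows2[[cc]]))))
    }
  })
})

test_that("invalid partition maps are rejected", {
  series <- tibble::tibble(census_year = 1976, division = "old1", age = 20,
                           in_count = 1, out_count = 0, net_count = 1)
  bad_shares <- tibble::tibble(old_division = "old1",
                               new_division = c("a", "b"), share = c(0.6, 0.5))
  expect_error(harmonize_flows(series, bad_shares), class = "mwrapop_validation_error")
  unmapped <- tibble::tibble(old_division = "other", new_division = "a", share = 1)
  expect_error(harmonize_flows(series, unmapped), class = "mwrapop_registry_error")
})

test_that("age proportions normalise nets within division-year", {
  base <- tibble::tibble(census_year = 2005, division = "d1", region = "R01",
                         age = c(15, 16), in_count = 0, out_count = 0,
                         net_count = c(2, 3))
  out <- age_proportions(base)
  expect_equal(out$X1, c(0.4, 0.6))
  expect_false(any(out$undefined))

  # mixed signs: proportions may leave [0, 1] but still sum to one
  mixed <- dplyr::mutate(base, net_count = c(4, -2))
  out2 <- age_proportions(mixed)
  expect_equal(out2$X1, c(2, -1))
  expect_equal(sum(out2$X1), 1)

  zero <- dplyr::mutate(base, net_count = c(5, -5))
  expect_warning(out3 <- age_proportions(zero),
                 class = "mwrapop_undefined_proportion")
  expect_true(all(out3$undefined))
  expect_true(all(out3$X1 == 0))
})

test_that("the net-migration model recovers a constant truth at all horizons", {
  reg <- admin_register(1, 2)
  x1_true <- c(0.1, 0.15, 0.2, 0.25, 0.3)  # sums to 1 over the 5 ages
  series <- tidyr::expand_grid(census_year = c(1976, 1987, 2005),
                               division = reg$division, age = 20:24) |>
    dplyr::mutate(X1 = x1_true[age - 19])
  fit <- suppressWarnings(
    fit_netmigration_model(series, reg, years = seq(2010, 2030, 10),
                           settings = tiny_settings(seed = 2, n_draws = 1500,
                                                    burn_in = 600)))
  med <- covariate_medians(fit)
  expect_equal(med$median, x1_true[med$age - 19], tolerance = 0.02)
  expect_s3_class(fit, "mwra_netmig_fit")
  expect_equal(n_draws_total(fit$draws), (1500 - 600) * 2)
})

test_that("with fixed scales the model matches the closed-form Gaussian posterior", {
  # single age, single division: the centred offsets vanish and the model
  # reduces to a random walk observed with noise, whose posterior mean has
  # a closed form through the tridiagonal precision matrix
  reg <- admin_register(1, 1)
  years <- c(1976, 1987, 2005, 2015)
  y_obs <- c(0.50, 0.56, 0.44)
  series <- tibble::tibble(census_year = c(1976, 1987, 2005),
                           division = reg$division, age = 25, X1 = y_obs)
  sd_obs <- 0.05; sd_rw <- 0.03; level_sd <- 10
  fit <- suppressWarnings(fit_netmigration_model(
    series, reg, years = 2015,
    settings = tiny_settings(seed = 3, n_draws = 6000, burn_in = 1000),
    priors = netmig_priors(level_sd = level_sd,
                           fixed = list(obs = sd_obs, rw = sd_rw,
                                        division = 1e-6, age = 1e-6))))

  K <- length(years)
  gap <- diff(years)
  tau_rw <- 1 / sd_rw^2
  tau_obs <- 1 / sd_obs^2
  Q <- matrix(0, K, K)
  Q[1, 1] <- 1 / level_sd^2
  for (k in seq_len(K - 1)) {
    tk <- tau_rw / gap[k]
    Q[k, k] <- Q[k, k] + tk
    Q[k + 1, k + 1] <- Q[k + 1, k + 1] + tk
    Q[k, k + 1] <- Q[k, k + 1] - tk
    Q[k + 1, k] <- Q[k + 1, k] - tk
  }
  b <- rep(0, K)
  obs_at <- match(series$census_year, years)
  for (i in seq_along(obs_at)) {
    Q[obs_at[i], obs_at[i]] <- Q[obs_at[i], obs_at[i]] + tau_obs
    b[obs_at[i]] <- b[obs_at[i]] + tau_obs * y_obs[i]
  }
  post_mean <- solve(Q, b)

  med <- covariate_medians(fit)
  expect_equal(med$median[match(years, med$year)], post_mean, tolerance = 0.02)
})
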