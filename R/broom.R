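#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Bayesian model fit
#'
#' One row per parameter: posterior median, standard deviation, 95%
#' credible interval, and convergence diagnostics. By default only scalar
#' parameters (coefficients and scales) are returned; `all = TRUE` adds
#' every monitored cell-level quantity.
#'
#' @param x An `mwra_fit` (population, net-migration, or fertility fit).
#' @param all Include cell-level parameters.
#' @param ... Unused.
#' @return A tibble `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `rhat`, `ess`.
#' @export
tidy.mwra_fit <- function(x, all = FALSE, ...) {
  m <- draws_matrix(x$draws)
  terms <- colnames(m)
  if (!all) terms <- terms[!grepl("\\[", terms) | grepl("^(beta|sigma)", terms)]
  s <- draws_summary(x$draws, terms = terms)
  sds <- apply(m[, s$term, drop = FALSE], 2, sd)
  out <- tibble::tibble(term = s$term, estimate = s$median, std.error = sds,
                        conf.low = s$cri_low, conf.high = s$cri_high)
  dplyr::left_join(out, x$diagnostics, by = "term")
}

#' Glance at a Bayesian model fit
#'
#' @param x An `mwra_fit`.
#' @param ... Unused.
#' @return A one-row tibble with draw counts, chains, worst R-hat,
#'   smallest effective sample size, and the convergence flag.
#' @export
glance.mwra_fit <- function(x, ...) {
  d <- x$diagnostics
  # for the population model, convergence is assessed on identified
  # functionals (see fit_population_model)
  if ("identified" %in% names(d)) d <- d[d$identified, ]
  tibble::tibble(
    n_draws = n_draws_total(x$draws),
    n_chains = x$settings$n_chains,
    n_parameters = ncol(draws_matrix(x$draws)),
    max_rhat = max(d$rhat, na.rm = TRUE),
    min_ess = min(d$ess, na.rm = TRUE),
    converged = x$converged
  )
}
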