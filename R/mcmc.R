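#' MCMC sampler settings
#'
#' Container for Markov chain Monte Carlo settings shared by the three
#' Bayesian model fits. `n_draws` is the total number of iterations per
#' chain including burn-in, so each chain contributes `n_draws - burn_in`
#' retained draws. Defaults follow the study design this package
#' implements: 10,000 iterations with a burn-in of 3,000 for the
#' net-migration and population models; pass `n_draws = 5000` for the
#' fertility model.
#'
#' @param n_draws Total iterations per chain (including burn-in).
#' @param burn_in Iterations discarded from the start of each chain.
#' @param n_chains Number of chains (>= 2 so that R-hat is defined).
#' @param seed Integer seed; chain c uses RNG seed `seed + c`.
#' @param n_adapt Adaptation iterations for the sampler (not retained).
#' @param sampler Sampler flavour for the population model:
#'   `"blocked-glm"` jointly updates all Gaussian latents (best mixing,
#'   cubic cost in the latent count), `"conjugate"` uses single-site
#'   conjugate updates (fast, mixes well when the data identify the
#'   coefficients strongly), `"auto"` (default) picks blocked updates for
#'   frames up to 400 cells and conjugate updates above.
#' @return An object of class `mwra_mcmc_settings`.
#' @export
mcmc_settings <- function(n_draws = 10000, burn_in = 3000, n_chains = 2,
                          seed = 1L, n_adapt = 500,
                          sampler = c("auto", "blocked-glm", "conjugate")) {
  sampler <- match.arg(sampler)
  n_draws <- assert_count(n_draws, "n_draws")
  burn_in <- assert_count(burn_in, "burn_in", min = 0)
  n_chains <- assert_count(n_chains, "n_chains", min = 2)
  if (n_draws <= burn_in) config_error("n_draws", "must exceed burn_in")
  structure(list(n_draws = n_draws, burn_in = burn_in, n_chains = n_chains,
                 seed = as.integer(seed), n_adapt = as.integer(n_adapt),
                 sampler = sampler),
            class = "mwra_mcmc_settings")
}

#' @export
print.mwra_mcmc_settings <- function(x, ...) {
  cat(sprintf("<mwra_mcmc_settings> %d draws (burn-in %d) x %d chains, seed %d\n",
              x$n_draws, x$burn_in, x$n_chains, x$seed))
  invisible(x)
}

# Run a JAGS model and return an `mwra_draws` object.
# `monitor` names the nodes to retain. Deterministic under settings$seed.
# `use_glm` loads JAGS's glm module for the compilation, which
# block-samples regression coefficients - essential for the correlated
# (beta, u) updates of the population model, but incompatible with the
# scaled random-walk precisions of the driver models.
jags_sample <- function(model_string, data, monitor, settings, use_glm = FALSE,
                        inits = list()) {
  stopifnot(inherits(settings, "mwra_mcmc_settings"))
  if (use_glm) {
    rjags::load.module("glm", quiet = TRUE)
    on.exit(try(rjags::unload.module("glm", quiet = TRUE), silent = TRUE))
  }
  inits <- lapply(seq_len(settings$n_chains), function(ch) {
    c(list(.RNG.name = "base::Wichmann-Hill",
           .RNG.seed = derive_seed(settings$seed, ch)),
      inits)
  })
  model <- rjags::jags.model(textConnection(model_string), data = data,
                             inits = inits, n.chains = settings$n_chains,
                             n.adapt = settings$n_adapt, quiet = TRUE)
  if (settings$burn_in > 0) update(model, settings$burn_in, progress.bar = "none")
  samp <- rjags::coda.samples(model, variable.names = monitor,
                              n.iter = settings$n_draws - settings$burn_in,
                              progress.bar = "none")
  as_mwra_draws(samp, settings)
}

#' Posterior draws container
#'
#' Labelled MCMC samples: a draws matrix (rows are retained iterations from
#' all chains stacked, columns are parameters) plus the chain index of each
#' row, so per-chain structure is available for convergence diagnostics.
#'
#' @param x A `coda::mcmc.list` (in `as_mwra_draws`) or `mwra_draws` object.
#' @param settings The `mcmc_settings` used to produce the draws.
#' @return `as_mwra_draws()` returns an object of class `mwra_draws`;
#'   `draws_matrix()` its draws matrix; `n_draws_total()` the number of
#'   retained draws across chains.
#' @export
as_mwra_draws <- function(x, settings = NULL) {
  stopifnot(inherits(x, "mcmc.list"))
  mats <- lapply(x, as.matrix)
  structure(list(
    draws = do.call(rbind, mats),
    chain = rep(seq_along(mats), vapply(mats, nrow, 1L)),
    settings = settings
  ), class = "mwra_draws")
}

#' @rdname as_mwra_draws
#' @export
draws_matrix <- function(x) {
  stopifnot(inherits(x, "mwra_draws"))
  x$draws
}

#' @rdname as_mwra_draws
#' @export
n_draws_total <- function(x) nrow(x$draws)

#' @export
print.mwra_draws <- function(x, ...) {
  cat(sprintf("<mwra_draws> %d draws x %d parameters (%d chains)\n",
              nrow(x$draws), ncol(x$draws), length(unique(x$chain))))
  invisible(x)
}

# median + 95% CrI for every column of a draws object / matrix
draws_summary <- function(x, terms = NULL) {
  m <- if (inherits(x, "mwra_draws")) x$draws else x
  if (!is.null(terms)) m <- m[, intersect(terms, colnames(m)), drop = FALSE]
  q <- apply(m, 2, function(v) c(median(v), cri(v)))
  tibble::tibble(term = colnames(m), median = unname(q[1, ]),
                 cri_low = unname(q[2, ]), cri_high = unname(q[3, ]))
}

# split the stacked draws matrix back into a list of per-chain matrices
chain_split <- function(x) {
  stopifnot(inherits(x, "mwra_draws"))
  lapply(sort(unique(x$chain)), function(ch) x$draws[x$chain == ch, , drop = FALSE])
}

# convergence table for a draws object; ESS only for at most `max_ess` columns
# (spectral ESS is costly on thousands of cell-level parameters)
convergence_table <- function(x, max_ess = 200) {
  chains <- chain_split(x)
  nm <- colnames(x$draws)
  rhat <- vapply(seq_along(nm), function(j) {
    gelman_rubin(vapply(chains, function(m) m[, j], numeric(nrow(chains[[1]]))))
  }, numeric(1))
  ess <- rep(NA_real_, length(nm))
  idx <- if (length(nm) > max_ess) {
    unique(round(seq(1, length(nm), length.out = max_ess)))
  } else seq_along(nm)
  ess[idx] <- vapply(idx, function(j) {
    sum(vapply(chains, function(m) unname(coda::effectiveSize(m[, j])), numeric(1)))
  }, numeric(1))
  tibble::tibble(term = nm, rhat = rhat, ess = ess)
}

# warn (never error) if the sampler looks unconverged; returns flag
flag_convergence <- function(diag, context, rhat_max = 1.1) {
  bad <- diag$term[!is.na(diag$rhat) & diag$rhat >= rhat_max]
  if (length(bad)) {
    rlang::warn(sprintf(
      "%s: %d parameter(s) with R-hat >= %.2f (worst: %s = %.3f); results returned, interpret with care",
      context, length(bad), rhat_max, diag$term[which.max(diag$rhat)], max(diag$rhat, na.rm = TRUE)),
      class = "mwrapop_convergence_warning")
    FALSE
  } else TRUE
}

# parse rjags names like "theta[3,1,2]" into an integer index matrix
parse_jags_index <- function(nms, var) {
  pat <- sprintf("^%s\\[", var)
  sel <- grepl(pat, nms)
  idx <- sub(sprintf("^%s\\[(.*)\\]$", var), "\\1", nms[sel])
  out <- do.call(rbind, lapply(strsplit(idx, ","), as.integer))
  list(which = which(sel), index = out)
}

# moderate starting values for free half-normal scales (JAGS would
# otherwise start truncated normals at zero, an infinite precision)
scale_inits <- function(priors, names_map) {
  free <- names_map[!names(names_map) %in% names(priors$fixed)]
  out <- lapply(names(free), function(k) max(0.1, priors[[k]] / 4))
  setNames(out, unname(free))
}

# half-normal or fixed scale node for a JAGS model string
scale_node <- function(name, prior_sd, fixed = NULL) {
  if (!is.null(fixed)) {
    sprintf("  %s <- %.10g\n  tau_%s <- pow(%s, -2)", name, fixed, sub("^sigma_", "", name), name)
  } else {
    # lower truncation at 1e-4 keeps the implied precision finite when the
    # posterior concentrates at zero variance
    sprintf("  %s ~ dnorm(0, %.10g) T(1.0E-4,)\n  tau_%s <- pow(%s, -2)",
            name, 1 / prior_sd^2, sub("^sigma_", "", name), name)
  }
}
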