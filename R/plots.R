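#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_ribbon facet_wrap
#'   labs theme_minimal
#' @export
ggplot2::autoplot

#' Fan chart of projected population trajectories
#'
#' Median trajectory with its 95% credible band per unit.
#'
#' @param object A [summarize_projection()] table.
#' @param level Which aggregation level to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mwra_projection_table <- function(object, level = "region", ...) {
  dat <- dplyr::filter(object, .data$level == !!level)
  ggplot(dat, aes(x = .data$year, y = .data$count_median)) +
    geom_ribbon(aes(ymin = .data$cri_low, ymax = .data$cri_high),
                fill = "steelblue", alpha = 0.25) +
    geom_line(colour = "steelblue") +
    facet_wrap(~unit, scales = "free_y") +
    labs(x = "Year", y = "Married women 15-49 (posterior median, 95% CrI)") +
    theme_minimal()
}

#' MCMC trace plot
#'
#' Per-chain trace of selected parameters, the visual convergence check
#' accompanying the Gelman-Rubin diagnostic.
#'
#' @param fit An `mwra_fit`.
#' @param pars Parameter names (default: all scalar parameters).
#' @return A ggplot object.
#' @export
plot_trace <- function(fit, pars = NULL) {
  m <- draws_matrix(fit$draws)
  pars <- pars %||% grep("\\[", colnames(m), value = TRUE, invert = TRUE)
  dat <- purrr::map_dfr(pars, function(p) {
    tibble::tibble(parameter = p, value = m[, p], chain = factor(fit$draws$chain))
  }) |>
    dplyr::group_by(.data$parameter, .data$chain) |>
    dplyr::mutate(iteration = dplyr::row_number()) |>
    dplyr::ungroup()
  ggplot(dat, aes(x = .data$iteration, y = .data$value, colour = .data$chain)) +
    geom_line(alpha = 0.7, linewidth = 0.3) +
    facet_wrap(~parameter, scales = "free_y") +
    labs(x = "Iteration (post burn-in)", y = NULL) +
    theme_minimal()
}
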