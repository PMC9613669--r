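#' Interpolate abridged survival probabilities to single age and year
#'
#' Converts five-year survival probabilities `px5` (probability of
#' surviving from exact age x to x+5), tabulated by 5-year age group and
#' 5-year calendar period, into a single-age single-year surface via a
#' bilinear scheme: each input value is anchored at its age-group midpoint
#' (`age_group_start + 2.5`) and period midpoint
#' (`period_start_year + 2.5`), interpolated linearly along age within each
#' period and then linearly along calendar year, with linear extrapolation
#' from the end segments beyond the last anchors (the behaviour of Stata's
#' `ipolate, epolate`). The default `mode = "direct"` interpolates the
#' five-year probabilities as-is into single-year values, reproducing the
#' source method; `mode = "fifth-root"` first converts anchors to
#' single-year scale as `px5^(1/5)`, the demographically standard
#' conversion. Results are clipped to (0, 1] and any clipping is reported.
#'
#' @param table Abridged life table: tibble with columns
#'   `period_start_year`, `age_group_start`, `px5` (all in (0, 1\]).
#' @param ages Target single ages.
#' @param years Target calendar years.
#' @param mode `"direct"` or `"fifth-root"` (see above).
#' @return A tibble with columns `age`, `year`, `px1`, with attribute
#'   `n_clipped` giving the number of clipped cells.
#' @examples
#' lt <- generate_life_tables(world_config())
#' surf <- interpolate_survival(lt)
#' @export
interpolate_survival <- function(table, ages = 15:49, years = 1976:2030,
                                 mode = c("direct", "fifth-root")) {
  mode <- match.arg(mode)
  req <- c("period_start_year", "age_group_start", "px5")
  if (!all(req %in% names(table))) {
    rlang::abort(sprintf("life table needs columns %s", paste(req, collapse = ", ")))
  }
  if (any(!is.finite(table$px5)) || any(table$px5 <= 0) || any(table$px5 > 1)) {
    rlang::abort("survival probabilities px5 must lie in (0, 1]",
                 class = "mwrapop_validation_error")
  }
  age_anchor <- sort(unique(table$age_group_start)) + 2.5
  per_anchor <- sort(unique(table$period_start_year)) + 2.5
  if (length(age_anchor) < 2 || length(per_anchor) < 2) {
    rlang::abort("need at least 2 age groups and 2 periods to interpolate")
  }
  v <- matrix(NA_real_, length(age_anchor), length(per_anchor))
  v[cbind(match(table$age_group_start + 2.5, age_anchor),
          match(table$period_start_year + 2.5, per_anchor))] <-
    if (mode == "fifth-root") table$px5^(1 / 5) else table$px5
  if (anyNA(v)) rlang::abort("life table must be complete over its age x period grid")

  # stage 1: along age at each period anchor; stage 2: along year
  by_age <- matrix(NA_real_, length(ages), length(per_anchor))
  for (j in seq_along(per_anchor)) {
    by_age[, j] <- lin_interp_extrap(age_anchor, v[, j], ages)
  }
  out <- matrix(NA_real_, length(ages), length(years))
  for (i in seq_along(ages)) {
    out[i, ] <- lin_interp_extrap(per_anchor, by_age[i, ], years)
  }

  n_clip <- sum(out > 1 | out <= 0)
  if (n_clip > 0) {
    rlang::inform(sprintf("interpolate_survival: clipped %d value(s) into (0, 1]", n_clip))
    out <- pmin(out, 1)
    out[out <= 0] <- 1e-6
  }
  int_if_whole <- function(v) if (all(v == round(v))) as.integer(v) else as.numeric(v)
  res <- tibble::tibble(age = rep(int_if_whole(ages), times = length(years)),
                        year = rep(int_if_whole(years), each = length(ages)),
                        px1 = as.vector(out))
  attr(res, "n_clipped") <- n_clip
  res
}
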