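#' Age-specific fertility rates from retrospective birth histories
#'
#' Person-period estimator of age-specific fertility rates (ASFR) in the
#' style of Stata's `tfr2`: each woman's observation time inside the
#' calendar window is partitioned by calendar month into (single age,
#' calendar year) cells; exposure is the weighted number of months divided
#' by 12, births are allocated to the cell containing each child's birth
#' month, and `asfr = weighted births / weighted woman-years`. Exposure
#' runs from the month of the woman's 15th birthday to her interview
#' (months strictly before the interview month count fully, the interview
#' month counts half) and is truncated at exact age 50. Sampling weights
#' and the all-women factor multiply both numerator and denominator, so a
#' constant factor cancels in the rate while woman-varying factors
#' re-weight it - the mechanism by which rates computed on surveyed women
#' are re-expressed for all women in the population.
#'
#' Cells with positive exposure and no births have `asfr = 0`; cells with
#' no exposure have `asfr = NA` and are flagged (`no_exposure`), never
#' treated as zero.
#'
#' @param histories Tibble of birth histories with columns `woman_id`,
#'   `region`, `woman_birth_cmc`, `interview_cmc`, `weight`,
#'   `all_women_factor`, and list-column `child_birth_cmcs` (CMC dates).
#' @param window Calendar window `c(first_year, last_year)` over which
#'   rates are computed.
#' @param by Grouping: `"region"` (default), `"none"` for a pooled
#'   national surface.
#' @param ages Single ages retained.
#' @return An ASFR surface: tibble with columns `age`, (`region`,) `year`,
#'   `births`, `exposure`, `asfr`, `no_exposure`.
#' @examples
#' cfg <- world_config(seed = 5, n_women = 200)
#' truth <- ground_truth(cfg)
#' bh <- generate_birth_histories(cfg, truth_asfr_surface(truth))
#' asfr <- compute_asfr(bh, window = c(1995, 2004))
#' @export
compute_asfr <- function(histories, window, by = c("region", "none"),
                         ages = 15:49) {
  by <- match.arg(by)
  req <- c("woman_id", "region", "woman_birth_cmc", "interview_cmc",
           "weight", "all_women_factor", "child_birth_cmcs")
  if (!all(req %in% names(histories))) {
    rlang::abort(sprintf("birth histories need columns %s", paste(req, collapse = ", ")))
  }
  if (any(histories$interview_cmc <= histories$woman_birth_cmc)) {
    rlang::abort("interview_cmc must exceed woman_birth_cmc",
                 class = "mwrapop_validation_error")
  }
  if (any(histories$weight <= 0) || any(histories$all_women_factor <= 0)) {
    rlang::abort("weights and all-women factors must be > 0",
                 class = "mwrapop_validation_error")
  }
  win_lo <- cmc(window[1], 1)
  win_hi <- cmc(window[2], 12)
  ages <- sort(as.integer(ages))

  n <- nrow(histories)
  birth_cmc <- as.integer(histories$woman_birth_cmc)
  iv <- as.integer(histories$interview_cmc)
  w <- histories$weight * histories$all_women_factor

  # exposure months: [15th birthday, interview], clipped to the window and
  # to age < 50; the interview month itself counts half
  start <- pmax(birth_cmc + 12L * min(ages), win_lo)
  end <- pmin(iv, birth_cmc + 12L * (max(ages) + 1L) - 1L, win_hi)
  n_m <- pmax(0L, end - start + 1L)
  wid <- rep.int(seq_len(n), n_m)
  m <- sequence(n_m, from = start)
  frac <- ifelse(m == iv[wid], 0.5, 1)
  exp_tab <- tibble::tibble(
    region = histories$region[wid],
    age = cmc_age(m, birth_cmc[wid]),
    year = cmc_year(m),
    exposure = frac / 12 * w[wid]
  ) |>
    dplyr::group_by(.data$region, .data$age, .data$year) |>
    dplyr::summarise(exposure = sum(.data$exposure), .groups = "drop")

  kids <- tibble::tibble(
    idx = rep.int(seq_len(n), lengths(histories$child_birth_cmcs)),
    bcmc = as.integer(unlist(histories$child_birth_cmcs, use.names = FALSE))
  )
  if (nrow(kids)) {
    kids <- dplyr::filter(kids, .data$bcmc >= win_lo, .data$bcmc <= win_hi)
    kids$age <- cmc_age(kids$bcmc, birth_cmc[kids$idx])
    kids <- dplyr::filter(kids, .data$age >= min(ages), .data$age <= max(ages))
  }
  birth_tab <- if (nrow(kids)) {
    tibble::tibble(region = histories$region[kids$idx], age = kids$age,
                   year = cmc_year(kids$bcmc), births = w[kids$idx]) |>
      dplyr::group_by(.data$region, .data$age, .data$year) |>
      dplyr::summarise(births = sum(.data$births), .groups = "drop")
  } else {
    tibble::tibble(region = character(), age = integer(), year = integer(),
                   births = numeric())
  }

  grid_regions <- if (by == "region") sort(unique(histories$region)) else "all"
  if (by == "none") {
    exp_tab$region <- "all"
    birth_tab$region <- "all"
    exp_tab <- dplyr::summarise(dplyr::group_by(exp_tab, .data$region, .data$age, .data$year),
                                exposure = sum(.data$exposure), .groups = "drop")
    if (nrow(birth_tab)) {
      birth_tab <- dplyr::summarise(dplyr::group_by(birth_tab, .data$region, .data$age, .data$year),
                                    births = sum(.data$births), .groups = "drop")
    }
  }
  out <- tidyr::expand_grid(region = grid_regions, age = ages,
                            year = seq(window[1], window[2])) |>
    dplyr::left_join(exp_tab, by = c("region", "age", "year")) |>
    dplyr::left_join(birth_tab, by = c("region", "age", "year")) |>
    dplyr::mutate(exposure = dplyr::coalesce(.data$exposure, 0),
                  births = dplyr::coalesce(.data$births, 0),
                  no_exposure = .data$exposure == 0,
                  asfr = dplyr::if_else(.data$exposure > 0,
                                        .data$births / .data$exposure, NA_real_)) |>
    dplyr::select("age", "region", "year", "births", "exposure", "asfr", "no_exposure")
  out
}

#' Total fertility rate of an ASFR surface
#'
#' Sums single-age rates over the reproductive span, the expected number of
#' births per woman surviving the span under the period schedule.
#'
#' @param surface An ASFR surface (from [compute_asfr()]), or any tibble
#'   with columns `asfr` plus grouping columns `region`/`year`.
#' @return A tibble with `region`, `year`, `tfr`.
#' @export
total_fertility <- function(surface) {
  surface |>
    dplyr::group_by(.data$region, .data$year) |>
    dplyr::summarise(tfr = sum(.data$asfr, na.rm = TRUE), .groups = "drop")
}
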