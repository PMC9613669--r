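#' Derive internal migration flows from census microdata
#'
#' Computes person-weighted in-, out- and net-migration of married women of
#' reproductive age by single age and division, from the current versus
#' previous division of residence: for a division d, in-migrants are women
#' currently in d whose previous division differs, out-migrants are women
#' currently elsewhere whose previous division is d, and net = in - out.
#' Rows with missing previous division contribute to neither flow (they are
#' treated as non-migrants), which preserves the closed-system zero sum of
#' net migration. The grid is completed with zeros over all register
#' divisions and requested ages.
#'
#' @param records Tibble of person records with columns `census_year`,
#'   `age`, `sex`, `marital_status`, `division_current`,
#'   `division_previous`, `person_weight`.
#' @param register Administrative register, see [admin_register()].
#' @param ages Integer ages retained (the reproductive span by default).
#' @return A tibble with columns `census_year`, `division`, `region`,
#'   `age`, `in_count`, `out_count`, `net_count`.
#' @examples
#' cfg <- world_config(seed = 3)
#' census <- generate_census(cfg, ground_truth(cfg))
#' flows <- compute_flows(census, cfg$register)
#' sum(flows$net_count)  # closed system: exactly zero
#' @export
compute_flows <- function(records, register, ages = 15:49) {
  register <- validate_register(register)
  check_divisions(records$division_current, register, "current division")
  check_divisions(records$division_previous, register, "previous division")

  mwra <- dplyr::filter(records,
                        .data$sex == "female",
                        .data$marital_status == "married",
                        .data$age %in% ages)
  grid <- tidyr::expand_grid(census_year = sort(unique(records$census_year)),
                             division = register$division,
                             age = sort(as.integer(ages)))
  if (nrow(mwra) == 0) {
    rlang::warn("no married women of reproductive age in `records`; returning empty series")
    out <- grid[0, ]
    out$in_count <- out$out_count <- out$net_count <- numeric(0)
    return(dplyr::left_join(out, register, by = "division")[,
      c("census_year", "division", "region", "age", "in_count", "out_count", "net_count")])
  }

  movers <- dplyr::filter(mwra, !is.na(.data$division_previous),
                          .data$division_previous != .data$division_current)
  inflow <- movers |>
    dplyr::group_by(census_year = .data$census_year,
                    division = .data$division_current, age = .data$age) |>
    dplyr::summarise(in_count = sum(.data$person_weight), .groups = "drop")
  outflow <- movers |>
    dplyr::group_by(census_year = .data$census_year,
                    division = .data$division_previous, age = .data$age) |>
    dplyr::summarise(out_count = sum(.data$person_weight), .groups = "drop")

  grid |>
    dplyr::left_join(inflow, by = c("census_year", "division", "age")) |>
    dplyr::left_join(outflow, by = c("census_year", "division", "age")) |>
    dplyr::mutate(in_count = dplyr::coalesce(.data$in_count, 0),
                  out_count = dplyr::coalesce(.data$out_count, 0),
                  net_count = .data$in_count - .data$out_count) |>
    dplyr::left_join(register, by = "division") |>
    dplyr::select("census_year", "division", "region", "age",
                  "in_count", "out_count", "net_count")
}

#' Proportionally partition counts across an administrative boundary change
#'
#' Re-expresses counts recorded on a historical division register on the
#' current register: each old division's counts are split across its
#' successor divisions according to fixed shares (which must sum to one per
#' old division), then summed by successor. Grand totals are conserved
#' exactly up to additive floating error.
#'
#' `harmonize_counts()` works on any cell table with a division column;
#' `harmonize_flows()` is the flow-series wrapper.
#'
#' @param x Tibble with a `division` column and one or more count columns.
#' @param map Partition map: tibble with columns `old_division`,
#'   `new_division`, `share`.
#' @param count_cols Names of the count columns to partition.
#' @param series A flow series as returned by [compute_flows()].
#' @return The input table re-indexed on the new register.
#' @export
harmonize_counts <- function(x, map,
                             count_cols = intersect(c("in_count", "out_count",
                                                      "net_count", "count"),
                                                    names(x))) {
  if (!all(c("old_division", "new_division", "share") %in% names(map))) {
    rlang::abort("partition map needs columns old_division, new_division, share")
  }
  sums <- tapply(map$share, map$old_division, sum)
  if (any(abs(sums - 1) > 1e-8)) {
    rlang::abort(sprintf("partition shares must sum to 1 per old division (violated for: %s)",
                         paste(names(sums)[abs(sums - 1) > 1e-8], collapse = ", ")),
                 class = "mwrapop_validation_error")
  }
  unmapped <- setdiff(unique(x$division), map$old_division)
  if (length(unmapped)) {
    rlang::abort(sprintf("division(s) missing from partition map: %s",
                         paste(head(unmapped, 5), collapse = ", ")),
                 class = "mwrapop_registry_error")
  }
  keys <- setdiff(names(x), c(count_cols, "division", "region"))
  x |>
    dplyr::inner_join(map, by = c(division = "old_division"),
                      relationship = "many-to-many") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(count_cols), ~ .x * .data$share)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "new_division")))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(count_cols), sum), .groups = "drop") |>
    dplyr::rename(division = "new_division")
}

#' @rdname harmonize_counts
#' @export
harmonize_flows <- function(series, map) {
  out <- harmonize_counts(series, map,
                          count_cols = c("in_count", "out_count", "net_count"))
  dplyr::relocate(out, "census_year", "division", "age")
}

#' Age proportions of net migration
#'
#' Expresses each age's net migration as a proportion of the division-year
#' total net migration: `X1(a, d, t) = net(a, d, t) / sum_a net(a, d, t)`.
#' Proportions over ages sum to one where defined, but individual values
#' may lie outside \[0, 1\] when age-specific nets have mixed signs. When a
#' division-year total is exactly zero the proportion is undefined; those
#' cells are flagged (`undefined = TRUE`), set to 0 - which asserts no age
#' pattern rather than inventing a direction of flow - and a warning is
#' emitted.
#'
#' @param series Flow series from [compute_flows()] (optionally
#'   harmonized).
#' @return The series with columns `X1` and `undefined` added.
#' @export
age_proportions <- function(series) {
  out <- series |>
    dplyr::group_by(.data$census_year, .data$division) |>
    dplyr::mutate(.total = sum(.data$net_count),
                  undefined = .data$.total == 0,
                  X1 = dplyr::if_else(.data$.total == 0, 0,
                                      .data$net_count / .data$.total)) |>
    dplyr::ungroup() |>
    dplyr::select(-".total")
  n_undef <- out |>
    dplyr::distinct(.data$census_year, .data$division, .data$undefined) |>
    dplyr::filter(.data$undefined) |>
    nrow()
  if (n_undef > 0) {
    rlang::warn(sprintf(
      "%d division-year(s) with zero total net migration; age proportions set to 0 and flagged",
      n_undef), class = "mwrapop_undefined_proportion")
  }
  out
}
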