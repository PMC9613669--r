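#' Administrative register of divisions nested in regions
#'
#' The spatial hierarchy of the model: second-level units (divisions)
#' nested in first-level units (regions), e.g. Cameroon's 58 divisions in
#' 10 regions. `admin_register()` builds a synthetic register with labelled
#' ids; any tibble with columns `division` and `region` (one row per
#' division, each division in exactly one region) is accepted wherever a
#' register is required.
#'
#' @param n_regions Number of regions.
#' @param divisions_per_region Number of divisions in each region.
#' @return A tibble with columns `division` and `region`.
#' @examples
#' admin_register(2, 3)
#' @export
admin_register <- function(n_regions = 2, divisions_per_region = 2) {
  n_regions <- assert_count(n_regions, "n_regions")
  divisions_per_region <- assert_count(divisions_per_region, "divisions_per_region")
  tibble::tibble(
    region = rep(sprintf("R%02d", seq_len(n_regions)), each = divisions_per_region),
    division = sprintf("%s-D%02d",
                       rep(sprintf("R%02d", seq_len(n_regions)), each = divisions_per_region),
                       rep(seq_len(divisions_per_region), times = n_regions))
  )[, c("division", "region")]
}

validate_register <- function(register) {
  if (!all(c("division", "region") %in% names(register))) {
    rlang::abort("register must have columns `division` and `region`")
  }
  if (anyDuplicated(register$division)) {
    rlang::abort("each division must appear exactly once in the register")
  }
  register
}

# error if any id is absent from the register
check_divisions <- function(ids, register, what = "division") {
  unknown <- setdiff(unique(ids[!is.na(ids)]), register$division)
  if (length(unknown)) {
    rlang::abort(
      sprintf("unknown %s id(s) not in the administrative register: %s",
              what, paste(head(unknown, 5), collapse = ", ")),
      class = "mwrapop_registry_error")
  }
  invisible(ids)
}
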