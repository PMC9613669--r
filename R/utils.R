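#' @importFrom rlang %||% abort warn inform .data
#' @importFrom stats median quantile rnorm rpois runif sd var cor rbinom setNames update
#' @importFrom utils head
NULL

# linear interpolation with linear extrapolation from the end segments
# (equivalent to Stata's `ipolate, epolate` on a sorted grid)
lin_interp_extrap <- function(x, y, xout) {
  stopifnot(length(x) == length(y), length(x) >= 2, !is.unsorted(x))
  i <- findInterval(xout, x, all.inside = TRUE)
  y[i] + (y[i + 1] - y[i]) / (x[i + 1] - x[i]) * (xout - x[i])
}

# 95% equal-tailed interval via type-7 (linear interpolation) quantiles
cri <- function(x, level = 0.95, type = 7) {
  a <- (1 - level) / 2
  stats::quantile(x, probs = c(a, 1 - a), type = type, names = FALSE)
}

#' Derive a per-stage child seed from a master seed
#'
#' Deterministic scheme used throughout the package so that pipeline stages
#' are independently re-runnable: `child = (master * 1009 + 9973 * stage) mod (2^31 - 1)`.
#'
#' @param master Integer master seed.
#' @param stage Integer stage index (>= 0).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 1009 + 9973 * as.numeric(stage)) %% (2^31 - 1))
}

# evaluate expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Century-month code (CMC) helpers
#'
#' The CMC encodes a calendar month as the number of months elapsed since
#' January 1900 (January 1900 = 1), the date convention of DHS birth
#' histories. `cmc()` builds codes, `cmc_year()` recovers the calendar year
#' and `cmc_month()` the month within the year.
#'
#' @param year Calendar year (>= 1900).
#' @param month Month 1-12.
#' @param x A CMC value.
#' @return Integer CMC, year, or month.
#' @export
cmc <- function(year, month = 1) {
  stopifnot(all(year >= 1900), all(month >= 1 & month <= 12))
  as.integer((year - 1900) * 12 + month)
}

#' @rdname cmc
#' @export
cmc_year <- function(x) 1900L + (as.integer(x) - 1L) %/% 12L

#' @rdname cmc
#' @export
cmc_month <- function(x) (as.integer(x) - 1L) %% 12L + 1L

# completed years of age at month `x` for someone born in month `birth`
cmc_age <- function(x, birth) (as.integer(x) - as.integer(birth)) %/% 12L

# stop with a configuration error naming the offending field
config_error <- function(field, msg) {
  rlang::abort(sprintf("invalid configuration field `%s`: %s", field, msg),
               class = "mwrapop_config_error", field = field)
}

assert_prob <- function(x, field, open_left = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    all(x <= 1) && all(if (open_left) x > 0 else x >= 0)
  if (!ok) config_error(field, "must lie in (0, 1]")
  invisible(x)
}

assert_count <- function(x, field, min = 1) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min && x == as.integer(x)
  if (!ok) config_error(field, sprintf("must be an integer >= %d", min))
  invisible(as.integer(x))
}
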