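#' @importFrom rlang %||% .data abort warn inform
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows n across all_of count pull distinct rename
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_int map_lgl imap pmap list_rbind
#' @importFrom stats approx coef vcov rnbinom rbinom runif quantile dnbinom
#'   dpois glm poisson logLik pnorm qnorm sd median setNames
#' @importFrom utils head tail
NULL

#' Round half away from zero at a given number of decimals
#'
#' Display rounding used for percentage columns: 53.5 becomes 54, unlike
#' [base::round()]'s round-half-even. Underlying values are never rounded,
#' only their printed form.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Numeric vector rounded half-up (half away from zero).
#' @examples
#' round_half_up(c(0.5, 1.5, 7.6502), 0)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# sequence of calendar months as a tibble(year, month), inclusive
month_grid <- function(start, end) {
  stopifnot(length(start) == 2, length(end) == 2)
  idx0 <- start[1] * 12L + (start[2] - 1L)
  idx1 <- end[1] * 12L + (end[2] - 1L)
  if (idx1 < idx0) abort("window end precedes window start")
  k <- idx0:idx1
  tibble(year = k %/% 12L, month = k %% 12L + 1L)
}

# 0-based month index of (year, month) relative to an origin (year0, month0)
month_index_from <- function(year, month, year0, month0) {
  12L * (year - year0) + (month - month0)
}

first_of_month <- function(year, month) {
  as.Date(sprintf("%04d-%02d-01", year, month))
}

# decimal time used for population interpolation: Jan 1 -> year + 0,
# Jul 1 -> year + 0.5; month m's offset value is taken at its first day
month_decimal <- function(year, month) year + (month - 1) / 12
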