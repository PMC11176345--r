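#' Commercial (half-up) rounding
#'
#' Rounds half-way cases away from zero, the convention used for all monetary
#' amounts (2 decimals) and reported percentages (1 decimal) in this package.
#' Base R's `round()` rounds half to even, which does not match printed
#' invoice arithmetic.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(c(0.125, 2.5, -2.5), 1)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  xp <- abs(x) * p
  # guard: binary representation of a decimal input may sit a few ulp below .5
  sign(x) * floor(xp + 0.5 + xp * 1e-12 + 1e-9) / p
}

#' Monetary rounding and exact summation
#'
#' `money()` rounds to whole cents (2 decimals, half-up). `money_sum()` sums
#' amounts that are already whole cents exactly, by accumulating integer cents;
#' this keeps totals bit-stable at every aggregation level (line, case, centre,
#' cohort).
#'
#' @param x numeric vector of amounts in euro.
#' @return `money()`: the rounded vector; `money_sum()`: a length-1 exact sum.
#' @export
money <- function(x) round_half_up(x, 2)

#' @rdname money
#' @export
money_sum <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(0)
  sum(round(x * 100)) / 100
}

# percentage to 1 decimal, half-up
pct1 <- function(x) round_half_up(x, 1)

#' Round a full-time-equivalent to the nearest quarter
#'
#' Staffing in the up-front allocation model is budgeted in quarter FTE steps;
#' ties (e.g. 0.875) round away from zero.
#'
#' @param x numeric FTE values.
#' @return `x` rounded to the nearest multiple of 0.25.
#' @examples
#' round_quarter(c(0.6, 0.875, 1.1))
#' @export
round_quarter <- function(x) {
  sign(x) * floor(abs(x) / 0.25 + 0.5 + 1e-9) * 0.25
}
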