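#' Iterated differencing of a numeric sequence
#'
#' Applies the first-difference operator `d` times to remove slow
#' non-stationary structure (trend) before model fitting. Order 0 is the
#' identity; each order shortens the sequence by one.
#'
#' @param x Numeric vector.
#' @param d Differencing order (>= 0).
#' @return Numeric vector of length `length(x) - d`.
#' @seealso [undifference()] for the exact inverse.
#' @export
difference <- function(x, d) {
  d <- as.integer(d)
  if (d < 0) abort_validation("`d` must be >= 0")
  if (length(x) <= d) {
    abort_validation("sequence of length ", length(x), " cannot be differenced ", d, " times")
  }
  if (d == 0) return(as.numeric(x))
  as.numeric(diff(x, differences = d))
}

#' Invert iterated differencing
#'
#' Reconstructs original-scale values from a `d`-times differenced sequence
#' by repeated cumulative summation, using the `d` trailing original values
#' that immediately precede `dx` as integration constants.
#' `undifference(difference(x, d), seeds, d)` reproduces the tail of `x`
#' exactly.
#'
#' @param dx Differenced values (e.g. forecasts on the differenced scale).
#' @param seeds The `d` original-scale values immediately preceding `dx`,
#'   oldest first.
#' @param d Differencing order; must equal `length(seeds)`.
#' @return Numeric vector of `length(dx)` original-scale values.
#' @export
undifference <- function(dx, seeds, d) {
  d <- as.integer(d)
  if (length(seeds) != d) {
    abort_validation("`seeds` must hold exactly d = ", d, " values, got ", length(seeds))
  }
  dx <- as.numeric(dx)
  if (d == 0) return(dx)
  # seed differences at each order: seeds of order j are the (d-j)-times
  # differenced values just before dx
  for (j in seq(d, 1)) {
    anchor <- if (j == 1) seeds[d] else utils::tail(difference(seeds, j - 1), 1)
    dx <- cumsum(c(anchor, dx))[-1]
  }
  dx
}
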