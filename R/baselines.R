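#' Fill a gap by linear interpolation
#'
#' Gap values lie on the straight line, in beat index, between the last
#' beat before the gap and the first beat after it. Interpolation is done
#' on the index axis because the true duration of the gap is unknown once
#' the beats are missing.
#'
#' @param series An [rr_series()].
#' @param gap A [gap_spec()]; must have at least one beat on each side.
#' @return An `rr_fill`.
#' @export
linear_fill <- function(series, gap) {
  series <- as_rr_series(series)
  check_gap(series, gap)
  if (gap$length == 0) return(new_rr_fill(series, numeric(), "linear", gap))
  if (gap$start == 1L || gap$start + gap$length - 1L == nrow(series)) {
    abort_validation("linear interpolation needs one anchor beat on each side of the gap")
  }
  i0 <- gap$start - 1L
  i1 <- gap$start + gap$length
  y0 <- series$rr_ms[i0]
  y1 <- series$rr_ms[i1]
  k <- seq_len(gap$length)
  pred <- y0 + (y1 - y0) * k / (gap$length + 1)
  insert_fill(series, gap, pred, "linear")
}

#' Fill a gap by cubic spline interpolation
#'
#' Fits a cubic spline, in beat index, through `context` beats on each side
#' of the gap and evaluates it at the gap indices. The spline uses
#' Forsythe-Malcolm-Moler end conditions (exact cubics through the boundary
#' points), so series sampled from any cubic polynomial of the index are
#' reproduced exactly.
#'
#' @inheritParams linear_fill
#' @param context Beats used on each side of the gap (default 10). At least
#'   4 context beats must be available in total.
#' @return An `rr_fill`.
#' @export
cubic_fill <- function(series, gap, context = 10) {
  series <- as_rr_series(series)
  check_gap(series, gap)
  if (gap$length == 0) return(new_rr_fill(series, numeric(), "cubic", gap))
  idx <- gap_idx(gap)
  left <- seq(max(1L, gap$start - context), gap$start - 1L)
  right_end <- gap$start + gap$length - 1L
  right <- seq(right_end + 1L, min(nrow(series), right_end + context))
  knots <- c(left[left >= 1], right[right <= nrow(series)])
  if (length(knots) < 4) {
    abort_validation("cubic interpolation needs at least 4 context beats, got ",
                     length(knots))
  }
  f <- stats::splinefun(knots, series$rr_ms[knots], method = "fmm")
  insert_fill(series, gap, f(idx), "cubic")
}

#' Correct a gap by deletion
#'
#' Removes the gap beats altogether: the series shortens by `gap$length`
#' and the cumulative beat times are recomputed, so the time axis contracts.
#' No values are predicted.
#'
#' @inheritParams linear_fill
#' @return An `rr_fill` whose `filled` series is `gap$length` beats shorter.
#' @export
deletion_fill <- function(series, gap) {
  series <- as_rr_series(series)
  check_gap(series, gap)
  idx <- gap_idx(gap)
  rr <- if (length(idx)) series$rr_ms[-idx] else series$rr_ms
  new_rr_fill(rr_series(rr, label = attr(series, "label")), numeric(),
              "deletion", gap)
}

#' Fill a gap with differenced Gaussian noise
#'
#' Tests whether any non-random structure remains after differencing: the
#' standard deviation of the `d`-times differenced pre-gap history is
#' estimated, `gap$length` increments are drawn from `Normal(0, sd)` (mean
#' zero — an empirical drift term would double-count the trend), and the
#' draws are integrated back from the last pre-gap value(s). Deterministic
#' under a fixed `seed`.
#'
#' @inheritParams linear_fill
#' @param d Differencing order used for the noise estimate (default 1; the
#'   successive differences of RR intervals are approximately Gaussian).
#' @param estimation_window Number of differenced increments used to
#'   estimate the standard deviation (requires `estimation_window + d`
#'   pre-gap beats); `NULL` (default) uses all pre-gap history. At least 2
#'   increments are required.
#' @param seed Optional integer seed; the fill is bit-reproducible given it.
#' @return An `rr_fill`.
#' @export
gaussian_fill <- function(series, gap, d = 1, estimation_window = NULL,
                          seed = NULL) {
  series <- as_rr_series(series)
  check_gap(series, gap)
  d <- as.integer(d)
  if (gap$length == 0) return(new_rr_fill(series, numeric(), "gaussian", gap))
  n_pre <- gap$start - 1L
  win <- if (is.null(estimation_window)) n_pre else as.integer(estimation_window) + d
  if (win < d + 2 || n_pre < win || n_pre < d) {
    abort_validation("not enough pre-gap history to estimate the differenced sd")
  }
  history <- series$rr_ms[seq_len(n_pre)]
  dwin <- difference(utils::tail(history, win), d)
  sd_hat <- if (length(dwin) >= 2) stats::sd(dwin) else 0
  draw <- function() stats::rnorm(gap$length, mean = 0, sd = sd_hat)
  z <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  pred <- undifference(z, seeds = utils::tail(history, d), d = d)
  insert_fill(series, gap, pred, "gaussian",
              config = list(d = d, sd = sd_hat, seed = seed))
}

#' Fill a gap with the ground truth (oracle)
#'
#' Re-inserts the values removed by [apply_gap()]. Useful only for
#' validating the evaluation pipeline: by construction every relative
#' metric error of this "corrector" is zero.
#'
#' @inheritParams linear_fill
#' @param truth Numeric vector of the true gap values, length `gap$length`.
#' @return An `rr_fill`.
#' @export
oracle_fill <- function(series, gap, truth) {
  series <- as_rr_series(series)
  check_gap(series, gap)
  if (length(truth) != gap$length) {
    abort_validation("`truth` must hold exactly gap$length values")
  }
  if (gap$length == 0) return(new_rr_fill(series, numeric(), "oracle", gap))
  insert_fill(series, gap, truth, "oracle")
}
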