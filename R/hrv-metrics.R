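#' HRV frequency bands
#'
#' The three standard spectral bands of the RR tachogram: very low frequency
#' (VLF) 0-0.04 Hz, low frequency (LF) 0.04-0.15 Hz and high frequency (HF)
#' 0.15-0.4 Hz. Bands are half-open `[lo, hi)`, so a frequency bin at exactly
#' 0.04 Hz counts as LF.
#'
#' @return A tibble with columns `band`, `lo`, `hi` (Hz).
#' @export
hrv_bands <- function() {
  tibble::tibble(
    band = c("vlf", "lf", "hf"),
    lo = c(0, 0.04, 0.15),
    hi = c(0.04, 0.15, 0.4)
  )
}

#' Root mean square of successive differences (RMSSD)
#'
#' `sqrt(mean((rr[k+1] - rr[k])^2))` over all successive interval pairs, in
#' ms. Invariant to constant offsets, equivariant under scaling.
#'
#' @param series An [rr_series()] (or data frame with `rr_ms`).
#' @return RMSSD in ms.
#' @export
rmssd <- function(series) {
  rr <- as_rr_series(series)$rr_ms
  sqrt(mean(diff(rr)^2))
}

#' Standard deviation of NN intervals (SDNN)
#'
#' Sample standard deviation (denominator n - 1) of the intervals, in ms.
#'
#' @inheritParams rmssd
#' @return SDNN in ms.
#' @export
sdnn <- function(series) {
  stats::sd(as_rr_series(series)$rr_ms)
}

#' Resample an RR series onto an even time grid
#'
#' The RR intervals form an irregularly sampled signal (the tachogram): the
#' value at beat time `t_k` is the interval `rr_k`. Spectral analysis needs
#' even sampling, so the tachogram is interpolated with a cubic spline
#' against the cumulative beat times and evaluated on a uniform grid from
#' the first to the last beat time at rate `fs`.
#'
#' @inheritParams rmssd
#' @param fs Sampling rate in Hz; must exceed twice the highest band edge
#'   (0.4 Hz). Default 4 Hz, the usual choice in HRV work.
#' @return A tibble with columns `time_s` and `rr_ms`.
#' @export
resample_even <- function(series, fs = 4) {
  series <- as_rr_series(series)
  if (nrow(series) < 4) {
    abort_validation("resampling needs at least 4 beats, got ", nrow(series))
  }
  if (fs <= 2 * 0.4) {
    abort_validation("`fs` must exceed 0.8 Hz (twice the HF upper edge)")
  }
  t_end <- series$time_s[nrow(series)]
  grid <- seq(0, t_end, by = 1 / fs)
  f <- stats::splinefun(series$time_s, series$rr_ms, method = "fmm")
  tibble::tibble(time_s = grid, rr_ms = f(grid))
}

#' Spectral band powers of the RR tachogram
#'
#' Computes the one-sided periodogram of the mean-removed, evenly resampled
#' tachogram via the FFT (no taper by default, optionally a Hann window) and
#' integrates the power spectral density over each band with the trapezoidal
#' rule. Total power is the sum of the three band powers, exactly.
#'
#' @inheritParams resample_even
#' @param bands Band definition table, by default [hrv_bands()].
#' @param window `"none"` (default) or `"hann"` taper applied before the FFT.
#' @return A one-row tibble with columns `vlf`, `lf`, `hf`, `tp` in ms^2.
#' @export
band_powers <- function(series, fs = 4, bands = hrv_bands(),
                        window = c("none", "hann")) {
  window <- match.arg(window)
  rs <- resample_even(series, fs = fs)
  x <- rs$rr_ms - mean(rs$rr_ms)
  n <- length(x)
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
    x <- x * w / sqrt(mean(w^2)) # preserve average power
  }
  spec <- abs(stats::fft(x))^2 / (fs * n) # two-sided PSD, ms^2/Hz
  half <- seq_len(floor(n / 2) + 1)
  psd <- spec[half]
  # fold the negative frequencies into the one-sided density
  interior <- setdiff(half, c(1L, if (n %% 2 == 0) floor(n / 2) + 1L))
  psd[interior] <- 2 * psd[interior]
  freq <- (half - 1) * fs / n
  power_in <- function(lo, hi) {
    idx <- which(freq >= lo & freq < hi)
    if (length(idx) < 2) return(0)
    trapz(freq[idx], psd[idx])
  }
  p <- purrr::map2_dbl(bands$lo, bands$hi, power_in)
  names(p) <- bands$band
  # tp is defined as the band sum; evaluate it in double precision so the
  # identity tp == vlf + lf + hf holds bit-exactly
  tibble::tibble(vlf = p[["vlf"]], lf = p[["lf"]], hf = p[["hf"]],
                 tp = p[["vlf"]] + p[["lf"]] + p[["hf"]])
}

trapz <- function(x, y) {
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' All six HRV summary metrics for one series
#'
#' Bundles the time-domain metrics ([rmssd()], [sdnn()]) with the spectral
#' band powers ([band_powers()]). `tp` is `vlf + lf + hf` by construction.
#'
#' @inheritParams band_powers
#' @return A one-row tibble with columns `rmssd`, `sdnn` (ms) and `vlf`,
#'   `lf`, `hf`, `tp` (ms^2).
#' @examples
#' s <- generate_rr(n_beats = 300, seed = 1)
#' hrv_metrics(s)
#' @export
hrv_metrics <- function(series, fs = 4, window = c("none", "hann")) {
  series <- as_rr_series(series)
  dplyr::bind_cols(
    tibble::tibble(rmssd = rmssd(series), sdnn = sdnn(series)),
    band_powers(series, fs = fs, window = window)
  )
}
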