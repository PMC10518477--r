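# shared fixture builders; oracles live next to the tests that use them

# RR series whose tachogram is a single sinusoid of `freq` Hz around a
# 1000 ms level, lasting `duration_s` seconds
sine_series <- function(freq, amp = 50, duration_s = 600, mean_rr = 1000) {
  rr <- numeric(0)
  t <- 0
  while (t < duration_s) {
    v <- mean_rr + amp * sin(2 * pi * freq * t)
    rr <- c(rr, v)
    t <- t + v / 1000
  }
  rr_series(rr)
}

# small random RR series for property loops
random_series <- function(n = 50) {
  rr_series(stats::runif(n, 600, 1100))
}

ramp_series <- function(n = 300, from = 800, by = 2) {
  rr_series(seq(from, by = by, length.out = n))
}
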