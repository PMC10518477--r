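# independent brute-force oracles, written against the formulas directly
oracle_rmssd <- function(rr) {
  d2 <- 0
  for (k in seq_len(length(rr) - 1)) d2 <- d2 + (rr[k + 1] - rr[k])^2
  sqrt(d2 / (length(rr) - 1))
}
oracle_sdnn <- function(rr) {
  m <- sum(rr) / length(rr)
  sqrt(sum((rr - m)^2) / (length(rr) - 1))
}

test_that("rmssd and sdnn match hand-evaluated values", {
  s <- rr_series(c(800, 810, 790, 805))
  # diffs (10, -20, 15): mean square 725/3; deviations from 801.25: ssq 218.75
  expect_equal(rmssd(s), sqrt(725 / 3), tolerance = 1e-12)
  expect_equal(round(rmssd(s), 3), 15.546)
  expect_equal(sdnn(s), sqrt(218.75 / 3), tolerance = 1e-12)
  expect_equal(round(sdnn(s), 3), 8.539)

  const <- rr_series(rep(800, 10))
  expect_identical(rmssd(const), 0)
  expect_identical(sdnn(const), 0)
})

test_that("time-domain metrics equal a brute-force evaluation on random series", {
  set.seed(101)
  for (i in 1:100) {
    s <- random_series(sample(4:60, 1))
    expect_equal(rmssd(s), oracle_rmssd(s$rr_ms), tolerance = 1e-9)
    expect_equal(sdnn(s), oracle_sdnn(s$rr_ms), tolerance = 1e-9)
  }
})

test_that("rmssd/sdnn are offset-invariant and scale-equivariant", {
  set.seed(5)
  for (i in 1:20) {
    s <- random_series(30)
    shifted <- rr_series(s$rr_ms + 100)
    scaled <- rr_series(s$rr_ms * 1.7)
    expect_equal(rmssd(shifted), rmssd(s))
    expect_equal(sdnn(shifted), sdnn(s))
    expect_equal(rmssd(scaled), 1.7 * rmssd(s))
    expect_equal(sdnn(scaled), 1.7 * sdnn(s))
  }
})

test_that("resampling reproduces constants and affine tachograms", {
  const <- resample_even(rr_series(rep(850, 20)))
  expect_equal(const$rr_ms, rep(850, nrow(const)))
  expect_equal(diff(const$time_s), rep(0.25, nrow(const) - 1))

  # rr linear in cumulative time: cubic interpolation must return the line
  rr <- numeric(0); t <- 0
  for (k in 1:50) {
    v <- 800 + 5 * t
    rr <- c(rr, v); t <- t + v / 1000
  }
  rs <- resample_even(rr_series(rr), fs = 4)
  expect_equal(rs$rr_ms, 800 + 5 * rs$time_s, tolerance = 1e-9)

  expect_error(resample_even(rr_series(c(800, 810, 790))),
               class = "hrvfill_validation_error")
  expect_error(resample_even(random_series(20), fs = 0.5),
               class = "hrvfill_validation_error")
})

test_that("a pure modulation concentrates >= 90% of power in its own band", {
  cases <- list(c(0.02, 1), c(0.10, 2), c(0.30, 3)) # freq, band column
  for (cs in cases) {
    bp <- band_powers(sine_series(cs[1]))
    expect_gt(bp[[cs[2]]], 0.9 * bp$tp)
  }
})

test_that("total power is the exact sum of the three bands, all non-negative", {
  set.seed(21)
  for (i in 1:15) {
    s <- random_series(sample(30:120, 1))
    bp <- band_powers(s)
    expect_identical(bp$tp, bp$vlf + bp$lf + bp$hf)
    expect_true(all(unlist(bp) >= 0))
  }
  const <- band_powers(rr_series(rep(900, 40)))
  expect_equal(unlist(const), c(vlf = 0, lf = 0, hf = 0, tp = 0),
               tolerance = 1e-18)
})

test_that("hrv_metrics composes the individual metrics unchanged", {
  s <- rr_series(c(800, 810, 790, 805, 800, 812, 795, 806))
  m <- hrv_metrics(s)
  expect_identical(m$rmssd, rmssd(s))
  expect_identical(m$sdnn, sdnn(s))
  expect_identical(m$tp, m$vlf + m$lf + m$hf)
  bp <- band_powers(s)
  expect_identical(m$lf, bp$lf)

  cm <- hrv_metrics(rr_series(rep(700, 30)))
  expect_equal(cm$rmssd + cm$sdnn + cm$tp, 0, tolerance = 1e-18)
})
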