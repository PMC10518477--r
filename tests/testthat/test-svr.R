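test_that("kernel functions match hand values and are symmetric", {
  lin <- svr_config(1, 0.1, "linear")
  expect_identical(kernel_eval(lin, c(1, 2), c(3, 4)), 11)

  rbf <- svr_config(1, 0.1, "rbf", gamma = 3.7)
  expect_identical(kernel_eval(rbf, c(1, 2, 3), c(1, 2, 3)), 1)

  poly <- svr_config(1, 0.1, "polynomial", gamma = 1, beta = 3, r = 1)
  expect_identical(kernel_eval(poly, c(1, 0), c(1, 0)), 8) # (1*1 + 1)^3

  sig <- svr_config(1, 0.1, "sigmoidal", gamma = 0.5, r = 0.2)
  expect_equal(kernel_eval(sig, c(1, 2), c(2, 1)), tanh(0.5 * 4 + 0.2))

  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(4); y <- rnorm(4)
    for (cfg in list(lin, rbf, poly, sig)) {
      expect_equal(kernel_eval(cfg, x, y), kernel_eval(cfg, y, x))
    }
  }
  expect_error(kernel_eval(lin, 1:2, 1:3), class = "hrvfill_validation_error")
})

test_that("lag matrix enumerates oldest-to-newest windows and next-value targets", {
  lm <- make_lag_matrix(c(1, 2, 3, 4), 2)
  expect_equal(lm$inputs, rbind(c(1, 2), c(2, 3)))
  expect_equal(lm$targets, c(3, 4))

  lm1 <- make_lag_matrix(c(5, 7, 9), 1)
  expect_equal(dim(lm1$inputs), c(2L, 1L))
  expect_equal(lm1$targets, c(7, 9))

  expect_error(make_lag_matrix(1:3, 3), class = "hrvfill_validation_error")
})

test_that("noiseless data inside the eps-tube is fitted to within eps", {
  set.seed(17)
  X <- matrix(runif(60, 0, 10), ncol = 2)
  y <- 2 * rowMeans(X) + 1
  cfg <- svr_config(C = 100, epsilon = 0.01, kernel = "linear",
                    sequence_length = 2)
  m <- fit_svr(X, y, cfg)
  pred <- apply(X, 1, function(row) predict_step(m, row))
  expect_lt(max(abs(pred - y)), 0.01 + 1e-3)
  # dual box constraint
  expect_true(all(abs(m$dual_coefs) <= 100 + 1e-8))
})

test_that("constant targets yield the degenerate no-support-vector optimum", {
  X <- matrix(rnorm(40), ncol = 2)
  for (cfg in list(svr_config(10, 0.1, "linear", sequence_length = 2),
                   svr_config(10, 0.1, "rbf", gamma = 1, sequence_length = 2))) {
    m <- fit_svr(X, rep(5, 20), cfg)
    expect_length(m$dual_coefs, 0)
    expect_lt(abs(predict_step(m, c(0.3, -0.2)) - 5), 0.1)
  }
  expect_error(fit_svr(matrix(1, 1, 2), 3,
                       svr_config(1, 0.1, "linear", sequence_length = 2)),
               class = "hrvfill_validation_error")
})

test_that("the stored dual expansion reproduces the solver's predictions", {
  # independent route: evaluate sum_i (a_i+ - a_i-) K(x, x_i) + b by hand
  set.seed(23)
  x <- as.numeric(arima.sim(list(ar = 0.6), n = 80)) + 10
  lag <- make_lag_matrix(x, 3)
  for (kernel in c("linear", "rbf", "polynomial", "sigmoidal")) {
    cfg <- svr_config(C = 10, epsilon = 0.05, kernel = kernel, gamma = 0.1,
                      beta = 3, r = 1, sequence_length = 3)
    m <- fit_svr(lag$inputs, lag$targets, cfg)
    w <- c(9.5, 10.2, 10.0)
    by_hand <- sum(vapply(seq_along(m$dual_coefs), function(i) {
      m$dual_coefs[i] * kernel_eval(cfg, w, m$support_vectors[i, ])
    }, 0)) + m$b
    expect_equal(predict_step(m, w), by_hand, tolerance = 1e-8)
  }
})

test_that("chained prediction shifts each forecast into the window", {
  stub <- function(w) w[length(w)] + 10
  expect_equal(cmr_forecast(stub, c(780, 790, 800), 3), c(810, 820, 830))
  expect_identical(cmr_forecast(stub, c(800), 0), numeric())

  set.seed(3)
  x <- as.numeric(arima.sim(list(ar = 0.5), n = 60)) + 20
  lag <- make_lag_matrix(x, 4)
  m <- fit_svr(lag$inputs, lag$targets,
               svr_config(1, 0.05, "linear", sequence_length = 4))
  w <- x[57:60]
  expect_identical(cmr_forecast(m, w, 1), predict_step(m, w))
  expect_error(cmr_forecast(m, x[58:60], 2),
               class = "hrvfill_validation_error")
})

test_that("CMR tracks a noiseless linear recurrence within 1%", {
  x <- 100 * 0.9^(0:40)
  lag <- make_lag_matrix(x, 1)
  m <- fit_svr(lag$inputs, lag$targets,
               svr_config(C = 100, epsilon = 0.001, kernel = "linear",
                          sequence_length = 1))
  pred <- cmr_forecast(m, 100, 3)
  expect_lt(max(abs(pred - c(90, 81, 72.9)) / c(90, 81, 72.9)), 0.01)
})

test_that("svr_fill continues a ramp exactly and checks its history needs", {
  s <- ramp_series(300)
  truth <- s$rr_ms[200:209]
  cfg <- svr_config(C = 1, epsilon = 0.01, kernel = "linear", d = 1,
                    sequence_length = 5)
  f <- svr_fill(s, gap_spec(200, 10), cfg, n_train = 50)
  expect_lt(max(abs(f$predicted - truth) / truth), 0.01)
  expect_identical(f$filled$rr_ms[-(200:209)], s$rr_ms[-(200:209)])

  id <- svr_fill(s, gap_spec(200, 0))
  expect_identical(id$filled$rr_ms, s$rr_ms)

  expect_error(svr_fill(s, gap_spec(21, 5), cfg, n_train = 200),
               class = "hrvfill_validation_error")
})
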