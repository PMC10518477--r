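test_that("relative error is absolute, in percent, with a zero-truth guard", {
  expect_equal(relative_error(100, 105), 5)
  expect_equal(relative_error(100, 100), 0)
  expect_equal(relative_error(40, 30), 25)
  expect_identical(relative_error(0, 0), 0)
  expect_true(is.na(relative_error(0, 3)))
})

test_that("the oracle filler scores 0% on every metric through the protocol", {
  for (seed in c(2, 7)) {
    s <- rr_preset("exercise", n_beats = 600, seed = seed)
    row <- evaluate_fill(s, "oracle")
    expect_equal(unname(unlist(row[c("rmssd", "sdnn", "vlf", "lf", "hf", "tp")])),
                 rep(0, 6))
  }
})

test_that("evaluate_fill matches a hand-composed pipeline for linear filling", {
  s <- rr_preset("rest", n_beats = 400, seed = 5)
  got <- evaluate_fill(s, "linear")

  # independent recomposition of the protocol, step by step
  n <- nrow(s)
  win <- (n - 250 + 1):n
  gap_start <- n - 250 + 121
  truth_m <- hrv_metrics(rr_series(s$rr_ms[win]))
  filled <- linear_fill(s, gap_spec(gap_start, 10))
  fill_m <- hrv_metrics(rr_series(filled$filled$rr_ms[win]))
  for (met in c("rmssd", "sdnn", "vlf", "lf", "hf", "tp")) {
    expect_equal(got[[met]],
                 abs(fill_m[[met]] - truth_m[[met]]) / truth_m[[met]] * 100)
  }
})

test_that("deletion is scored on the shortened window", {
  s <- rr_preset("rest", n_beats = 300, seed = 6)
  got <- evaluate_fill(s, "deletion")
  n <- nrow(s)
  gap_start <- n - 250 + 121
  kept <- setdiff((n - 250 + 1):n, gap_start:(gap_start + 9))
  fill_m <- hrv_metrics(rr_series(s$rr_ms[kept]))
  truth_m <- hrv_metrics(rr_series(s$rr_ms[(n - 250 + 1):n]))
  expect_equal(got$sdnn,
               abs(fill_m$sdnn - truth_m$sdnn) / truth_m$sdnn * 100)
})

test_that("the default grids enumerate the documented scopes", {
  ag <- arima_grid()
  expect_identical(nrow(ag), 525L) # 5 x 3 x 5 x 7
  expect_identical(nrow(dplyr::distinct(ag)), 525L)

  sg <- svr_grid()
  counts <- table(sg$kernel)
  expect_identical(as.integer(counts[c("linear", "rbf", "sigmoidal", "polynomial")]),
                   c(336L, 1344L, 2688L, 8064L))
  expect_identical(nrow(sg), 12432L)
  expect_true(all(is.na(sg$gamma[sg$kernel == "linear"])))
})

test_that("grid search agrees with an independent brute-force enumeration", {
  datasets <- list(rr_preset("rest", n_beats = 400, seed = 8),
                   rr_preset("exercise", n_beats = 400, seed = 9))
  grid <- tidyr::expand_grid(method = "arima", p = 1:3, d = 0L, q = 1L,
                             sequence_length = c(15L, 30L))
  gs <- grid_search(datasets, grid)

  # brute force, outside the module: loop configs, average over the datasets
  # each config fits, exclude configs with any failure, take the argmin
  bf <- vapply(seq_len(nrow(grid)), function(i) {
    errs <- lapply(datasets, function(s) {
      tryCatch(
        {
          row <- evaluate_fill(
            s, "arima",
            config = arima_config(grid$p[i], grid$d[i], grid$q[i],
                                  grid$sequence_length[i])
          )
          c(row$lf, row$hf)
        },
        hrvfill_fit_error = function(e) NULL
      )
    })
    ok <- !vapply(errs, is.null, TRUE)
    m <- if (any(ok)) colMeans(do.call(rbind, errs[ok])) else rep(NA_real_, 2)
    c(criterion = m[[1]] + m[[2]], failed = sum(!ok))
  }, numeric(2))
  eligible <- which(bf["failed", ] == 0)
  best_bf <- eligible[which.min(bf["criterion", eligible])]
  expect_equal(gs$best$criterion, unname(bf["criterion", best_bf]))
  expect_identical(gs$best$p, grid$p[best_bf])
  expect_identical(gs$best$sequence_length, grid$sequence_length[best_bf])
  expect_equal(gs$results$criterion, unname(bf["criterion", ]))
  expect_identical(gs$results$n_failed, as.integer(bf["failed", ]))

  # single-config grid: that config wins by construction
  one <- grid_search(datasets, grid[3, ])
  expect_identical(one$best$p, grid$p[3])

  td <- tidy(gs)
  expect_identical(nrow(td), 6L)
  gl <- glance(gs)
  expect_identical(gl$n_configs, 6L)
  expect_equal(gl$best_criterion, gs$best$criterion)
})

test_that("configs that fail to fit are flagged and excluded from the argmin", {
  datasets <- list(rr_preset("rest", n_beats = 400, seed = 10))
  # sequence_length 5 cannot identify ARIMA(3,1,3): guaranteed failure row
  grid <- tibble::tibble(method = "arima", p = c(3L, 1L), d = c(1L, 0L),
                         q = c(3L, 1L), sequence_length = c(5L, 30L))
  gs <- grid_search(datasets, grid)
  expect_identical(gs$results$n_failed, c(1L, 0L))
  expect_identical(gs$best$p, 1L)
  expect_error(grid_search(datasets, grid[1, ]), class = "hrvfill_fit_error")
})

test_that("summaries report mean, median and per-metric worst case", {
  one <- tibble::tibble(method = "m", rmssd = 3, sdnn = 1, vlf = 2, lf = 5,
                        hf = 4, tp = 2)
  sm <- summarize_errors(one)
  expect_equal(sm$lf, rep(5, 3))

  errs <- tibble::tibble(rmssd = c(1, 2, 9), sdnn = c(1, 2, 9),
                         vlf = c(1, 2, 9), lf = c(1, 2, 9), hf = c(9, 2, 1),
                         tp = c(1, 2, 9))
  sm2 <- summarize_errors(errs)
  expect_equal(sm2$lf[sm2$statistic == "mean"], 4)
  expect_equal(sm2$lf[sm2$statistic == "median"], 2)
  expect_equal(sm2$lf[sm2$statistic == "worst"], 9)
  # worst taken per metric: lf's max and hf's max come from different rows
  expect_equal(sm2$hf[sm2$statistic == "worst"], 9)
  expect_error(summarize_errors(errs[0, ]), class = "hrvfill_validation_error")
})

test_that("a single-size sweep reduces to one evaluate_fill mean", {
  datasets <- list(rr_preset("exercise", n_beats = 600, seed = 12),
                   rr_preset("exercise", n_beats = 600, seed = 13))
  sw <- training_size_sweep(datasets, sizes = 50)
  expect_identical(names(sw), c("n_train", "lf", "hf", "n_datasets"))
  per <- vapply(datasets, function(s) {
    row <- evaluate_fill(s, "svr", n_train = 50)
    c(row$lf, row$hf)
  }, numeric(2))
  expect_equal(sw$lf, mean(per[1, ]))
  expect_equal(sw$hf, mean(per[2, ]))
})
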