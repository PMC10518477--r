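#' Evaluation protocol settings
#'
#' The correction-evaluation protocol: the last `test_length` beats of a
#' recording form the test window (so everything before and inside the
#' pre-gap part of the window can serve as training history), a gap of
#' `gap_length` beats is introduced in the middle of the window (see
#' [middle_gap()]), the gap is filled, and the HRV metrics of the filled
#' window are compared with those of the intact window. 250 beats is one to
#' two minutes of data — the usual ultra-short-term HRV recording length.
#'
#' @param test_length Test-window length in beats (default 250).
#' @param gap_length Gap length in beats (default 10).
#' @param fs Resampling rate for the spectral metrics (Hz, default 4).
#' @return A list of class `protocol_spec`.
#' @export
protocol_spec <- function(test_length = 250, gap_length = 10, fs = 4) {
  test_length <- as.integer(test_length)
  gap_length <- as.integer(gap_length)
  if (gap_length < 0 || gap_length >= test_length) {
    abort_validation("`gap_length` must be in [0, test_length)")
  }
  structure(list(test_length = test_length, gap_length = gap_length, fs = fs),
            class = "protocol_spec")
}

#' Relative error of a corrected metric, in percent
#'
#' `|corrected - true| / |true| * 100`. When the true value is zero the
#' ratio is undefined: a corrected value that is also zero counts as 0%
#' error, anything else returns `NA` (excluded from aggregation, and
#' countable by the caller).
#'
#' @param true True metric value.
#' @param corrected Metric value after correction.
#' @return Non-negative percent error, or `NA` when undefined.
#' @export
relative_error <- function(true, corrected) {
  dplyr::case_when(
    true != 0 ~ abs(corrected - true) / abs(true) * 100,
    corrected == 0 ~ 0,
    .default = NA_real_
  )
}

#' The fill methods known to the evaluation protocol
#' @return Character vector of method names.
#' @export
fill_methods <- function() {
  c("arima", "svr", "linear", "cubic", "deletion", "gaussian", "oracle")
}

# build the right config object from a grid row / list
config_from_row <- function(row) {
  row <- as.list(row)
  if (identical(row$method, "arima")) {
    arima_config(row$p, row$d, row$q, row$sequence_length)
  } else if (identical(row$method, "svr")) {
    svr_config(
      C = row$C, epsilon = row$epsilon, kernel = row$kernel,
      gamma = row$gamma %||% NA_real_, beta = row$beta %||% NA_integer_,
      r = row$r %||% NA_real_, d = row$d, sequence_length = row$sequence_length
    )
  } else {
    abort_validation("grid rows must have method 'arima' or 'svr'")
  }
}

#' Evaluate one fill method on one recording
#'
#' Runs the full protocol on a single series: carve the test window,
#' introduce the central gap, fill it with `method`, and report the relative
#' error of each of the six HRV metrics (filled window vs intact window).
#' For `"deletion"` the metrics are computed on the shortened window with
#' its recomputed, contracted time axis.
#'
#' @param series An [rr_series()], long enough for the test window plus the
#'   method's pre-gap training needs.
#' @param method One of [fill_methods()].
#' @param config Hyperparameter bundle for `"arima"`/`"svr"` (defaults to
#'   the recommended presets); ignored otherwise.
#' @param n_train SVR training rows (default 200).
#' @param protocol A [protocol_spec()].
#' @param seed Seed forwarded to the Gaussian-noise filler.
#' @return A one-row tibble: `dataset`, `method`, and the relative errors
#'   (%) `rmssd`, `sdnn`, `vlf`, `lf`, `hf`, `tp`.
#' @examples
#' s <- rr_preset("exercise", seed = 1)
#' evaluate_fill(s, "linear")
#' @export
evaluate_fill <- function(series, method = fill_methods(), config = NULL,
                          n_train = 200, protocol = protocol_spec(),
                          seed = NULL) {
  series <- as_rr_series(series)
  method <- match.arg(method)
  n <- nrow(series)
  if (n < protocol$test_length) {
    abort_validation("series has ", n, " beats; the protocol needs at least ",
                     protocol$test_length)
  }
  win_start <- n - protocol$test_length + 1L
  gap <- gap_spec(
    win_start - 1L + middle_gap(protocol$test_length, protocol$gap_length),
    protocol$gap_length
  )
  truth_window <- rr_series(series$rr_ms[win_start:n])
  truth_metrics <- hrv_metrics(truth_window, fs = protocol$fs)

  fill <- switch(method,
    arima = arima_fill(series, gap, config %||% arima_recommended()),
    svr = svr_fill(series, gap, config %||% svr_recommended(), n_train = n_train),
    linear = linear_fill(series, gap),
    cubic = cubic_fill(series, gap),
    deletion = deletion_fill(series, gap),
    gaussian = gaussian_fill(series, gap, seed = seed),
    oracle = oracle_fill(series, gap, truth = series$rr_ms[gap_idx(gap)])
  )
  win_len <- protocol$test_length - (if (method == "deletion") gap$length else 0L)
  filled_window <- rr_series(utils::tail(fill$filled$rr_ms, win_len))
  filled_metrics <- hrv_metrics(filled_window, fs = protocol$fs)

  errs <- purrr::map2_dbl(truth_metrics, filled_metrics, relative_error)
  dplyr::bind_cols(
    tibble::tibble(dataset = attr(series, "label"), method = method),
    tibble::as_tibble(as.list(errs))
  )
}

#' Default ARIMA hyperparameter grid
#'
#' The full search scope: `p` 1-5, `d` 0-2, `q` 1-5, sequence length
#' {5, 10, 15, 20, 30, 50, 100} — 525 configurations. Combinations too short
#' to identify (sequence length <= p + d + q) are kept in the grid; their
#' fits fail and are flagged by [grid_search()].
#'
#' @return A tibble with columns `method`, `p`, `d`, `q`, `sequence_length`.
#' @export
arima_grid <- function() {
  dplyr::mutate(
    tidyr::expand_grid(p = 1:5, d = 0:2, q = 1:5,
                       sequence_length = c(5L, 10L, 15L, 20L, 30L, 50L, 100L)),
    method = "arima", .before = 1
  )
}

#' Default SVR hyperparameter grid
#'
#' The full search scope: `C` {0.1, 1, 10, 100}, `epsilon`
#' {0.01, 0.05, 0.1, 1}, all four kernels, `gamma` {0.1, 1, 10, 100},
#' `beta` {3, 4, 5}, `r` {0, 1}, `d` 0-2, sequence length
#' {5, 10, 15, 20, 30, 50, 100}. Axes a kernel does not use are collapsed
#' (left `NA`) so equivalent configurations are evaluated once: 336 linear +
#' 1344 RBF + 2688 sigmoidal + 8064 polynomial = 12432 distinct rows.
#'
#' @return A tibble with columns `method`, `C`, `epsilon`, `kernel`,
#'   `gamma`, `beta`, `r`, `d`, `sequence_length`.
#' @export
svr_grid <- function() {
  Cs <- c(0.1, 1, 10, 100); eps <- c(0.01, 0.05, 0.1, 1)
  gammas <- c(0.1, 1, 10, 100); seqs <- c(5L, 10L, 15L, 20L, 30L, 50L, 100L)
  base <- list(C = Cs, epsilon = eps, d = 0:2, sequence_length = seqs)
  g <- dplyr::bind_rows(
    rlang::exec(tidyr::expand_grid, kernel = "linear", !!!base),
    rlang::exec(tidyr::expand_grid, kernel = "rbf", gamma = gammas, !!!base),
    rlang::exec(tidyr::expand_grid, kernel = "sigmoidal", gamma = gammas,
                r = c(0, 1), !!!base),
    rlang::exec(tidyr::expand_grid, kernel = "polynomial", gamma = gammas,
                beta = 3:5, r = c(0, 1), !!!base)
  )
  dplyr::mutate(
    dplyr::select(g, "C", "epsilon", "kernel", "gamma", "beta", "r", "d",
                  "sequence_length"),
    method = "svr", .before = 1
  )
}

#' Grid search for the best hyperparameters
#'
#' Evaluates every configuration in `grid` on every dataset, averages the
#' per-metric relative errors across datasets, and selects the
#' configuration minimising the summed mean LF and HF errors — the
#' selection criterion `argmin(LFerr + HFerr)`, chosen because the LF and HF
#' band powers are the hardest metrics to predict and dominate overall
#' error. Configurations whose fit fails on any dataset are retained in the
#' table, flagged (`n_failed`), and excluded from the argmin; ties break to
#' the earliest row in grid declaration order.
#'
#' @param datasets A list of [rr_series()] (or a single series).
#' @param grid A tibble of configurations, e.g. from [arima_grid()],
#'   [svr_grid()], or hand-built with a `method` column plus the
#'   hyperparameter columns.
#' @param protocol A [protocol_spec()].
#' @param n_train SVR training rows.
#' @return An object of class `hrv_grid_search`: `results` (the grid with
#'   mean errors, `criterion` and `n_failed` per row), `best` (the winning
#'   row). [tidy()] returns the full table, [glance()] a one-row summary.
#' @export
grid_search <- function(datasets, grid, protocol = protocol_spec(),
                        n_train = 200) {
  if (inherits(datasets, "rr_series")) datasets <- list(datasets)
  if (length(datasets) < 1) abort_validation("need at least one dataset")
  if (nrow(grid) < 1) abort_validation("empty grid")
  metric_cols <- c("rmssd", "sdnn", "vlf", "lf", "hf", "tp")

  eval_config <- function(row) {
    config <- config_from_row(row)
    per_ds <- purrr::map(datasets, function(s) {
      tryCatch(
        evaluate_fill(s, method = row$method, config = config,
                      n_train = n_train, protocol = protocol),
        hrvfill_fit_error = function(e) NULL
      )
    })
    ok <- !purrr::map_lgl(per_ds, is.null)
    means <- if (any(ok)) {
      dplyr::summarise(
        dplyr::bind_rows(per_ds[ok]),
        dplyr::across(dplyr::all_of(metric_cols), ~ mean(.x, na.rm = TRUE))
      )
    } else {
      tibble::as_tibble(stats::setNames(as.list(rep(NA_real_, 6)), metric_cols))
    }
    dplyr::mutate(means, n_failed = sum(!ok))
  }

  scores <- purrr::map(seq_len(nrow(grid)), function(i) eval_config(grid[i, ]))
  results <- dplyr::bind_cols(grid, dplyr::bind_rows(scores))
  results$criterion <- results$lf + results$hf
  eligible <- which(results$n_failed == 0 & !is.na(results$criterion))
  if (length(eligible) == 0) {
    abort_fit("every configuration in the grid failed to fit")
  }
  best_i <- eligible[which.min(results$criterion[eligible])]
  structure(
    list(results = results, best = results[best_i, ], protocol = protocol,
         n_train = n_train),
    class = "hrv_grid_search"
  )
}

#' @export
print.hrv_grid_search <- function(x, ...) {
  cat(sprintf(
    "<hrv_grid_search> %d configurations on %s; best criterion (LF+HF error) %.3g%%\n",
    nrow(x$results), x$best$method[1], x$best$criterion[1]
  ))
  print(x$best)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a grid-search result
#'
#' One row per configuration with its mean relative errors, the selection
#' criterion (mean LF + HF error) and the number of datasets it failed on.
#'
#' @param x An `hrv_grid_search`.
#' @param ... Unused.
#' @export
tidy.hrv_grid_search <- function(x, ...) {
  tibble::as_tibble(x$results)
}

#' One-row summary of a grid search
#'
#' @param x An `hrv_grid_search`.
#' @param ... Unused.
#' @export
glance.hrv_grid_search <- function(x, ...) {
  tibble::tibble(
    n_configs = nrow(x$results),
    n_failed_configs = sum(x$results$n_failed > 0),
    best_criterion = x$best$criterion[1],
    best_method = x$best$method[1]
  )
}

#' SVR training-size sweep
#'
#' Re-runs the protocol for a range of training-set sizes to show how much
#' error-free history the SVR corrector actually needs; around 200 samples
#' the LF and HF errors typically level out.
#'
#' @param datasets A list of [rr_series()].
#' @param sizes Integer vector of `n_train` values.
#' @param config An [svr_config()].
#' @param protocol A [protocol_spec()].
#' @return A tibble of class `hrv_sweep` with one row per size: `n_train`,
#'   mean `lf` and `hf` relative errors (%), `n_datasets`.
#' @export
training_size_sweep <- function(datasets, sizes, config = svr_recommended(),
                                protocol = protocol_spec()) {
  if (inherits(datasets, "rr_series")) datasets <- list(datasets)
  if (any(sizes < 1)) abort_validation("`sizes` must be positive")
  out <- purrr::map_dfr(as.integer(sizes), function(nt) {
    per <- dplyr::bind_rows(purrr::map(
      datasets, evaluate_fill, method = "svr", config = config,
      n_train = nt, protocol = protocol
    ))
    tibble::tibble(
      n_train = nt,
      lf = mean(per$lf, na.rm = TRUE),
      hf = mean(per$hf, na.rm = TRUE),
      n_datasets = nrow(per)
    )
  })
  class(out) <- c("hrv_sweep", class(out))
  out
}

#' Mean, median and worst-case error summaries
#'
#' Aggregates per-dataset relative errors the way multi-subject results are
#' usually reported: arithmetic mean, median, and the per-metric maximum
#' across datasets (the worst case for each metric may come from different
#' datasets). Undefined errors (`NA`) are excluded.
#'
#' @param errors A tibble of per-dataset rows as returned by
#'   [evaluate_fill()]; a `method` column, if present, is grouped over.
#' @return A tibble with columns `method` (if supplied), `statistic`
#'   (`"mean"`, `"median"`, `"worst"`) and the six metric errors.
#' @export
summarize_errors <- function(errors) {
  if (nrow(errors) < 1) abort_validation("no error rows to summarise")
  metric_cols <- intersect(c("rmssd", "sdnn", "vlf", "lf", "hf", "tp"),
                           names(errors))
  long <- tidyr::pivot_longer(
    errors, dplyr::all_of(metric_cols),
    names_to = "metric", values_to = "error"
  )
  keys <- intersect("method", names(errors))
  agg <- dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(c(keys, "metric")))),
    mean = mean(error, na.rm = TRUE),
    median = stats::median(error, na.rm = TRUE),
    worst = max(error, na.rm = TRUE),
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(
    tidyr::pivot_longer(agg, dplyr::all_of(c("mean", "median", "worst")),
                        names_to = "statistic", values_to = "error"),
    names_from = "metric", values_from = "error"
  )
  dplyr::arrange(
    dplyr::select(wide, dplyr::all_of(c(keys, "statistic", metric_cols))),
    dplyr::across(dplyr::all_of(keys))
  )
}
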