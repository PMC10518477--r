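#' ARIMA hyperparameter bundle
#'
#' Holds the four ARIMA hyperparameters: AR order `p`, differencing order
#' `d`, MA order `q`, and the sequence length — the number of points
#' immediately preceding a gap that the model is trained on.
#'
#' @param p AR order (integer >= 0).
#' @param d Differencing order (integer >= 0).
#' @param q MA order (integer >= 0).
#' @param sequence_length Number of training points.
#' @return A list of class `arima_config`.
#' @seealso [arima_recommended()] for the packaged preset, [arima_grid()]
#'   for the full search scope.
#' @export
arima_config <- function(p, d, q, sequence_length) {
  p <- as.integer(p); d <- as.integer(d); q <- as.integer(q)
  sequence_length <- as.integer(sequence_length)
  if (any(is.na(c(p, d, q, sequence_length))) ||
      p < 0 || d < 0 || q < 0 || sequence_length < 1) {
    abort_validation("arima_config needs p, d, q >= 0 and sequence_length >= 1")
  }
  structure(list(p = p, d = d, q = q, sequence_length = sequence_length),
            class = "arima_config")
}

#' @export
print.arima_config <- function(x, ...) {
  cat(sprintf("<arima_config> ARIMA(%d,%d,%d), sequence length %d\n",
              x$p, x$d, x$q, x$sequence_length))
  invisible(x)
}

#' Recommended ARIMA preset
#'
#' `ARIMA(2,0,2)` trained on the 30 points before the gap: differencing
#' order zero and MA order two, with the AR order having little influence,
#' are what the hyperparameter search singles out for exercise HRV data.
#'
#' @return An [arima_config()].
#' @export
arima_recommended <- function() arima_config(p = 2, d = 0, q = 2, sequence_length = 30)

#' Construct an ARIMA model object directly from coefficients
#'
#' Mainly useful for testing forecast semantics with known coefficients;
#' [fit_arima()] builds the same structure from an estimated fit. The model
#' on the `d`-times differenced scale is
#' `x_t = c + sum(phi_i x_{t-i}) + sum(theta_j e_{t-j}) + e_t`.
#'
#' @param config An [arima_config()]; `p` and `q` must match the coefficient
#'   lengths.
#' @param constant Constant term `c` on the differenced scale.
#' @param phi AR weights, length `p`.
#' @param theta MA weights, length `q`.
#' @param history Original-scale training values, most recent last. Needs at
#'   least `p + d` values to start the recursion.
#' @param residuals In-sample one-step errors aligned with the (differenced)
#'   history; the last `q` are used to start forecasting. Defaults to zeros.
#' @return A list of class `arima_model`.
#' @export
arima_model <- function(config, constant = 0, phi = numeric(), theta = numeric(),
                        history, residuals = rep(0, config$q)) {
  if (length(phi) != config$p || length(theta) != config$q) {
    abort_validation("phi/theta lengths must equal config p/q")
  }
  if (length(history) < config$p + config$d) {
    abort_validation("history must hold at least p + d values")
  }
  structure(
    list(config = config, constant = constant, phi = as.numeric(phi),
         theta = as.numeric(theta), history = as.numeric(history),
         residuals = as.numeric(residuals), fit = NULL),
    class = "arima_model"
  )
}

#' Fit an ARIMA model to a training window
#'
#' Estimates the AR and MA weights and the constant by (conditional-sum +)
#' maximum likelihood on the `d`-times differenced training values. The
#' constant term is included only when `d = 0`, the standard identifiability
#' convention. Non-convergent or degenerate fits raise a classed
#' `hrvfill_fit_error` carrying the offending config, never silent `NaN`s.
#'
#' @param train Numeric vector of exactly `config$sequence_length`
#'   original-scale values, oldest first.
#' @param config An [arima_config()].
#' @return An [arima_model()] with the estimated coefficients, the training
#'   history and the in-sample innovations retained for forecasting.
#' @examples
#' set.seed(1)
#' x <- as.numeric(arima.sim(list(ar = 0.8), n = 200)) + 800
#' fit_arima(x, arima_config(1, 0, 0, sequence_length = 200))
#' @export
fit_arima <- function(train, config) {
  train <- as.numeric(train)
  if (length(train) != config$sequence_length) {
    abort_validation(
      "training window has ", length(train), " values; config requires ",
      config$sequence_length
    )
  }
  if (config$sequence_length <= config$p + config$d + config$q) {
    abort_fit("sequence length ", config$sequence_length,
              " too short to identify ARIMA(", config$p, ",", config$d, ",",
              config$q, ")", config = config)
  }
  dx <- difference(train, config$d)
  if (stats::sd(dx) == 0) {
    # deterministic limit: the differenced window is exactly constant, so the
    # zero-innovation-variance model (constant = that value, no AR/MA part)
    # is the exact ML solution; the optimiser cannot reach it numerically
    return(arima_model(
      config, constant = dx[1], phi = rep(0, config$p),
      theta = rep(0, config$q), history = train
    ))
  }
  # default CSS-ML first; its CSS initialisation occasionally lands in a
  # non-stationary region, in which case full ML is attempted before the
  # config is declared a failure
  attempt <- function(method) {
    tryCatch(
      suppressWarnings(stats::arima(
        train, order = c(config$p, config$d, config$q),
        include.mean = config$d == 0, method = method
      )),
      error = function(e) e
    )
  }
  fit <- attempt("CSS-ML")
  if (inherits(fit, "error")) fit <- attempt("ML")
  if (inherits(fit, "error")) {
    abort_fit("ARIMA(", config$p, ",", config$d, ",", config$q,
              ") fit failed: ", conditionMessage(fit), config = config)
  }
  if (!is.null(fit$code) && fit$code != 0) {
    abort_fit("ARIMA optimiser did not converge (code ", fit$code, ")",
              config = config)
  }
  co <- stats::coef(fit)
  phi <- unname(co[grep("^ar", names(co))])
  theta <- unname(co[grep("^ma", names(co))])
  mu <- if ("intercept" %in% names(co)) unname(co["intercept"]) else 0
  if (anyNA(c(phi, theta, mu))) {
    abort_fit("ARIMA fit produced missing coefficients", config = config)
  }
  m <- arima_model(
    config, constant = mu * (1 - sum(phi)), phi = phi, theta = theta,
    history = train,
    residuals = as.numeric(fit$residuals)
  )
  m$fit <- fit
  m
}

#' Forecast from an ARIMA model
#'
#' Iterates the model recursion on the differenced scale with all future
#' errors set to zero (their conditional expectation), then integrates the
#' forecasts back to the original scale using the tail of the training
#' history as seeds.
#'
#' @param model An [arima_model()].
#' @param h Forecast horizon (>= 0 steps).
#' @return Numeric vector of `h` original-scale forecasts.
#' @export
arima_forecast <- function(model, h) {
  h <- as.integer(h)
  if (is.na(h) || h < 0) abort_validation("`h` must be >= 0")
  if (h == 0) return(numeric())
  cfg <- model$config
  dx <- difference(model$history, cfg$d)
  eps <- model$residuals
  out <- numeric(h)
  for (i in seq_len(h)) {
    ar_part <- if (cfg$p > 0) sum(model$phi * rev(utils::tail(dx, cfg$p))) else 0
    ma_part <- if (cfg$q > 0) sum(model$theta * rev(utils::tail(eps, cfg$q))) else 0
    out[i] <- model$constant + ar_part + ma_part
    dx <- c(dx, out[i])
    eps <- c(eps, 0)
  }
  undifference(out, seeds = utils::tail(model$history, cfg$d), d = cfg$d)
}

#' Fill a gap by ARIMA forecasting
#'
#' Fits an ARIMA model on the `sequence_length` beats immediately preceding
#' the gap and inserts its `gap$length`-step forecast. Beats outside the gap
#' are untouched.
#'
#' @param series An [rr_series()].
#' @param gap A [gap_spec()].
#' @param config An [arima_config()]; defaults to [arima_recommended()].
#' @return An `rr_fill` with the corrected series and the inserted values.
#' @export
arima_fill <- function(series, gap, config = arima_recommended()) {
  series <- as_rr_series(series)
  check_gap(series, gap)
  if (gap$length == 0) {
    return(new_rr_fill(series, numeric(), "arima", gap, config))
  }
  n_pre <- gap$start - 1L
  if (n_pre < config$sequence_length) {
    abort_validation(
      "only ", n_pre, " beats precede the gap; ARIMA training needs ",
      config$sequence_length
    )
  }
  train <- series$rr_ms[seq(n_pre - config$sequence_length + 1L, n_pre)]
  model <- fit_arima(train, config)
  pred <- arima_forecast(model, gap$length)
  insert_fill(series, gap, pred, "arima", config)
}

# replace the gap values and rebuild the series (times recomputed)
insert_fill <- function(series, gap, values, method, config = NULL) {
  rr <- series$rr_ms
  rr[gap_idx(gap)] <- values
  if (any(rr <= 0)) {
    abort_fit("filled values are not all positive; method '", method,
              "' produced an invalid RR series", config = config)
  }
  new_rr_fill(rr_series(rr, label = attr(series, "label")), values, method,
              gap, config)
}
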