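#' SVR hyperparameter bundle
#'
#' Holds the epsilon-insensitive support vector regression hyperparameters:
#' regularization constant `C`, margin `epsilon`, the kernel and its
#' parameters (`gamma`, polynomial degree `beta`, offset `r`), the
#' differencing order `d` applied before training, and the sequence length —
#' the number of back-lagged observations used as the model input.
#' Parameters a kernel does not use may be left `NA`.
#'
#' @param C Regularization constant (> 0).
#' @param epsilon Margin width (>= 0).
#' @param kernel One of `"linear"`, `"polynomial"`, `"sigmoidal"`, `"rbf"`.
#' @param gamma Kernel scale (> 0); unused by the linear kernel.
#' @param beta Polynomial degree (integer); polynomial kernel only.
#' @param r Kernel offset; polynomial and sigmoidal kernels only.
#' @param d Differencing order applied to the data before training.
#' @param sequence_length Number of lagged inputs per prediction.
#' @return A list of class `svr_config`.
#' @seealso [svr_recommended()], [svr_grid()].
#' @export
svr_config <- function(C, epsilon,
                       kernel = c("linear", "polynomial", "sigmoidal", "rbf"),
                       gamma = NA_real_, beta = NA_integer_, r = NA_real_,
                       d = 0, sequence_length = 5) {
  kernel <- match.arg(kernel)
  if (C <= 0) abort_validation("`C` must be > 0")
  if (epsilon < 0) abort_validation("`epsilon` must be >= 0")
  needs_gamma <- kernel != "linear"
  if (needs_gamma && (is.na(gamma) || gamma <= 0)) {
    abort_validation("kernel '", kernel, "' needs gamma > 0")
  }
  if (kernel == "polynomial" && (is.na(beta) || is.na(r))) {
    abort_validation("polynomial kernel needs `beta` and `r`")
  }
  if (kernel == "sigmoidal" && is.na(r)) {
    abort_validation("sigmoidal kernel needs `r`")
  }
  d <- as.integer(d); sequence_length <- as.integer(sequence_length)
  if (d < 0 || sequence_length < 1) {
    abort_validation("`d` must be >= 0 and `sequence_length` >= 1")
  }
  structure(
    list(C = C, epsilon = epsilon, kernel = kernel, gamma = gamma,
         beta = as.integer(beta), r = r, d = d,
         sequence_length = sequence_length),
    class = "svr_config"
  )
}

#' @export
print.svr_config <- function(x, ...) {
  cat(sprintf(
    "<svr_config> %s kernel, C=%g, eps=%g, d=%d, sequence length %d\n",
    x$kernel, x$C, x$epsilon, x$d, x$sequence_length
  ))
  invisible(x)
}

#' Recommended SVR preset
#'
#' Linear kernel, `C = 1`, `epsilon = 0.01`, no differencing, sequence
#' length 5 — the configuration the hyperparameter search selects for
#' exercise HRV data (the value of `C` matters little).
#'
#' @return An [svr_config()].
#' @export
svr_recommended <- function() {
  svr_config(C = 1, epsilon = 0.01, kernel = "linear", d = 0, sequence_length = 5)
}

#' Evaluate a kernel function
#'
#' The four Mercer kernels used by the SVR corrector:
#' linear `x . xi`; polynomial `(gamma x . xi + r)^beta`;
#' sigmoidal `tanh(gamma x . xi + r)`; RBF `exp(-gamma ||x - xi||^2)`.
#'
#' @param config An [svr_config()] naming the kernel and its parameters.
#' @param x,xi Numeric vectors of equal length.
#' @return The scalar kernel value.
#' @export
kernel_eval <- function(config, x, xi) {
  if (length(x) != length(xi)) {
    abort_validation("`x` and `xi` must have the same dimension")
  }
  switch(config$kernel,
    linear = sum(x * xi),
    polynomial = (config$gamma * sum(x * xi) + config$r)^config$beta,
    sigmoidal = tanh(config$gamma * sum(x * xi) + config$r),
    rbf = exp(-config$gamma * sum((x - xi)^2))
  )
}

#' Build a lag matrix for one-step-ahead regression
#'
#' Row `k` holds `L` consecutive values `x[k], ..., x[k+L-1]` ordered oldest
#' to newest, and its target is the next value `x[k+L]`.
#'
#' @param x Numeric vector, length > `sequence_length`.
#' @param sequence_length Number of lags `L` per row.
#' @return A list with `inputs` (matrix, `length(x) - L` rows by `L`
#'   columns) and `targets` (numeric vector).
#' @export
make_lag_matrix <- function(x, sequence_length) {
  L <- as.integer(sequence_length)
  n <- length(x)
  if (n <= L) {
    abort_validation("need more than sequence_length = ", L, " values, got ", n)
  }
  idx <- seq_len(n - L)
  inputs <- matrix(0, nrow = length(idx), ncol = L)
  for (j in seq_len(L)) inputs[, j] <- x[idx + j - 1L]
  list(inputs = inputs, targets = x[idx + L])
}

#' Fit an epsilon-insensitive SVR on lagged inputs
#'
#' Solves the epsilon-insensitive regression (sequential minimal
#' optimisation on the dual, honouring the box constraint
#' `|a_i+ - a_i-| <= C`); the fitted predictor is the kernel expansion
#' `y(x) = sum_i (a_i+ - a_i-) K(x, x_i) + b`. Inputs are *not* standardised
#' by default; set `standardize = TRUE` to opt in. When every target fits
#' inside the epsilon-tube around a constant, the dual solution has no
#' support vectors; that degenerate optimum (all dual coefficients zero,
#' `b` the midrange of the targets) is returned explicitly.
#'
#' @param inputs Lag-row matrix from [make_lag_matrix()].
#' @param targets Numeric response vector, one per row.
#' @param config An [svr_config()].
#' @param standardize Standardise inputs and targets before fitting
#'   (default `FALSE`).
#' @param tol Solver termination tolerance (default 1e-3).
#' @return A list of class `svr_model` with the fitted `e1071::svm` object
#'   (or the degenerate constant model), the support vectors, dual
#'   coefficients `a_i+ - a_i-` and bias `b`.
#' @export
fit_svr <- function(inputs, targets, config, standardize = FALSE, tol = 1e-3) {
  inputs <- as.matrix(inputs)
  if (nrow(inputs) < 2) {
    abort_validation("SVR needs at least 2 training rows, got ", nrow(inputs))
  }
  if (nrow(inputs) != length(targets)) {
    abort_validation("`inputs` rows and `targets` length differ")
  }
  kern <- c(linear = "linear", polynomial = "polynomial",
            sigmoidal = "sigmoid", rbf = "radial")[[config$kernel]]
  fit <- tryCatch(
    e1071::svm(
      x = inputs, y = targets, type = "eps-regression", kernel = kern,
      cost = config$C, epsilon = config$epsilon,
      gamma = if (is.na(config$gamma)) 1 else config$gamma,
      degree = if (is.na(config$beta)) 3 else config$beta,
      coef0 = if (is.na(config$r)) 0 else config$r,
      scale = standardize, tolerance = tol, fitted = FALSE
    ),
    error = function(e) {
      if (grepl("empty", conditionMessage(e), ignore.case = TRUE)) NULL else {
        abort_fit("SVR fit failed: ", conditionMessage(e), config = config)
      }
    }
  )
  if (!is.null(fit) && length(fit$coefs) == 0) fit <- NULL
  if (is.null(fit)) {
    # all targets inside the tube around a constant: optimum has w = 0
    return(structure(
      list(config = config, fit = NULL,
           support_vectors = inputs[0, , drop = FALSE],
           dual_coefs = numeric(),
           b = (min(targets) + max(targets)) / 2),
      class = "svr_model"
    ))
  }
  structure(
    list(config = config, fit = fit,
         support_vectors = unname(as.matrix(fit$SV)),
         dual_coefs = as.numeric(fit$coefs),
         b = -fit$rho),
    class = "svr_model"
  )
}

#' @export
print.svr_model <- function(x, ...) {
  cat(sprintf("<svr_model> %s kernel, %d support vectors, b = %.4g\n",
              x$config$kernel, length(x$dual_coefs), x$b))
  invisible(x)
}

#' One-step prediction from a model or stub function
#'
#' Generic used by [cmr_forecast()]: given the last `sequence_length`
#' observed (possibly differenced) values, predict the next one. A plain
#' function can serve as the model, which makes the chaining semantics
#' testable independently of any fitted regressor.
#'
#' @param model An `svr_model`, or a function `window -> next value`.
#' @param window Numeric vector of lagged values, oldest first.
#' @return The predicted next value (scalar).
#' @export
predict_step <- function(model, window) UseMethod("predict_step")

#' @export
predict_step.svr_model <- function(model, window) {
  if (length(window) != model$config$sequence_length) {
    abort_validation("window length ", length(window), " != sequence length ",
                     model$config$sequence_length)
  }
  if (is.null(model$fit)) return(model$b)
  as.numeric(stats::predict(model$fit, matrix(window, nrow = 1)))
}

#' @export
predict_step.function <- function(model, window) model(window)

#' Chained multioutput regression (CMR) forecast
#'
#' Multi-step forecasting with a one-step model: predict the next value,
#' shift it into the input window, and repeat until `h` values have been
#' produced. With `h = 1` this is exactly a single one-step prediction.
#'
#' @param model A fitted `svr_model` or a one-step function (see
#'   [predict_step()]).
#' @param window The last `sequence_length` observed values, oldest first.
#' @param h Forecast horizon (>= 0).
#' @return Numeric vector of `h` chained predictions.
#' @export
cmr_forecast <- function(model, window, h) {
  h <- as.integer(h)
  if (is.na(h) || h < 0) abort_validation("`h` must be >= 0")
  window <- as.numeric(window)
  if (inherits(model, "svr_model") &&
      length(window) != model$config$sequence_length) {
    abort_validation("window length ", length(window), " != sequence length ",
                     model$config$sequence_length)
  }
  out <- numeric(h)
  for (i in seq_len(h)) {
    out[i] <- predict_step(model, window)
    window <- c(window[-1], out[i])
  }
  out
}

#' Fill a gap by SVR forecasting with chained prediction
#'
#' Differences the pre-gap history `d` times, builds the lag matrix, keeps
#' the most recent `n_train` rows, fits the SVR, forecasts `gap$length`
#' steps by chaining on the differenced scale, and undifferences once at the
#' end using the last pre-gap values as seeds.
#'
#' @param series An [rr_series()].
#' @param gap A [gap_spec()].
#' @param config An [svr_config()]; defaults to [svr_recommended()].
#' @param n_train Number of training rows (lagged-input/target pairs) kept,
#'   default 200.
#' @param standardize Passed to [fit_svr()].
#' @return An `rr_fill`.
#' @export
svr_fill <- function(series, gap, config = svr_recommended(), n_train = 200,
                     standardize = FALSE) {
  series <- as_rr_series(series)
  check_gap(series, gap)
  if (gap$length == 0) {
    return(new_rr_fill(series, numeric(), "svr", gap, config))
  }
  n_pre <- gap$start - 1L
  need <- n_train + config$d + config$sequence_length
  if (n_pre < need) {
    abort_validation(
      "only ", n_pre, " beats precede the gap; SVR with n_train = ", n_train,
      ", d = ", config$d, ", sequence length ", config$sequence_length,
      " needs ", need
    )
  }
  history <- series$rr_ms[seq_len(n_pre)]
  dx <- difference(history, config$d)
  lag <- make_lag_matrix(dx, config$sequence_length)
  keep <- utils::tail(seq_along(lag$targets), n_train)
  model <- fit_svr(lag$inputs[keep, , drop = FALSE], lag$targets[keep], config,
                   standardize = standardize)
  window <- utils::tail(dx, config$sequence_length)
  pred_d <- cmr_forecast(model, window, gap$length)
  pred <- undifference(pred_d, seeds = utils::tail(history, config$d),
                       d = config$d)
  insert_fill(series, gap, pred, "svr", config)
}
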