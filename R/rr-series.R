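#' Construct an RR-interval series
#'
#' The central container of the package: an ordered sequence of RR intervals
#' (the times between successive heartbeats, in milliseconds) together with
#' the cumulative beat times they imply. Beat times are anchored at zero, so
#' beat `k` occurs at the running sum of all *earlier* intervals divided by
#' 1000 (seconds).
#'
#' @param rr_ms Numeric vector of RR interval lengths in milliseconds. All
#'   values must be finite and strictly positive, and at least two intervals
#'   are required (no HRV metric is defined on fewer).
#' @param label Optional free-text identifier carried along as an attribute.
#'
#' @return A tibble of class `rr_series` with columns `beat` (1-based index),
#'   `time_s` (cumulative beat time in seconds, starting at 0) and `rr_ms`.
#'
#' @examples
#' rr_series(c(800, 810, 790))
#' @export
rr_series <- function(rr_ms, label = NULL) {
  rr_ms <- as.numeric(rr_ms)
  if (length(rr_ms) < 2) {
    abort_validation("an RR series needs at least 2 intervals, got ", length(rr_ms))
  }
  if (anyNA(rr_ms) || any(!is.finite(rr_ms))) {
    abort_validation("RR intervals must all be finite and non-missing")
  }
  if (any(rr_ms <= 0)) {
    bad <- which(rr_ms <= 0)[1]
    abort_validation(
      "RR intervals must be strictly positive; interval ", bad,
      " is ", rr_ms[bad], " ms"
    )
  }
  out <- tibble::tibble(
    beat = seq_along(rr_ms),
    time_s = rr_times(rr_ms),
    rr_ms = rr_ms
  )
  class(out) <- c("rr_series", class(out))
  attr(out, "label") <- label %||% ""
  out
}

# cumulative beat times: beat k sits at the sum of the intervals before it
rr_times <- function(rr_ms) {
  c(0, cumsum(rr_ms[-length(rr_ms)])) / 1000
}

#' Coerce a data frame to an RR series
#'
#' Accepts any data frame with an `rr_ms` column; beat times are recomputed
#' from the intervals so the cumulative-time invariant always holds.
#'
#' @param x A data frame with a numeric `rr_ms` column.
#' @param label Optional identifier (defaults to the existing label, if any).
#' @return An [rr_series()] tibble.
#' @export
as_rr_series <- function(x, label = NULL) {
  if (inherits(x, "rr_series") && is.null(label)) {
    return(rr_series(x$rr_ms, label = attr(x, "label")))
  }
  if (!is.data.frame(x) || is.null(x$rr_ms)) {
    abort_validation("`x` must be a data frame with an `rr_ms` column")
  }
  rr_series(x$rr_ms, label = label %||% attr(x, "label"))
}

#' @export
print.rr_series <- function(x, ...) {
  lab <- attr(x, "label")
  dur <- sum(x$rr_ms) / 1000
  cat(sprintf(
    "# RR series%s: %d beats, %.1f s, mean RR %.1f ms\n",
    if (nzchar(lab %||% "")) paste0(" '", lab, "'") else "",
    nrow(x), dur, mean(x$rr_ms)
  ))
  NextMethod()
}

#' Read an RR-interval series from disk
#'
#' Two plain-text formats are supported: `txt` has one interval (ms) per
#' line with `#`-prefixed comment lines allowed, and `csv` has two columns
#' `time_s, rr_ms` (header row optional). For `csv` the time column is
#' checked against the running sum of the intervals and must agree to within
#' 1 ms; beat times are always recomputed from the intervals.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"txt"` or `"csv"`.
#' @param label Identifier for the series; defaults to the file name.
#' @return An [rr_series()] tibble.
#' @export
read_rr <- function(path, format = c("auto", "txt", "csv"), label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_validation("file not found: ", path)
  }
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "txt"
  }
  label <- label %||% basename(path)
  lines <- readLines(path, warn = FALSE)
  if (format == "txt") {
    keep <- !grepl("^\\s*(#|$)", lines)
    vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
    if (anyNA(vals)) {
      bad <- which(keep)[which(is.na(vals))[1]]
      abort_parse("non-numeric value on line ", bad, " of ", path)
    }
    return(rr_series(vals, label = label))
  }
  # csv: optional single header row, then time_s,rr_ms
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  has_header <- length(lines) > 0 &&
    is.na(suppressWarnings(as.numeric(strsplit(lines[1], ",")[[1]][1])))
  if (has_header) {
    lines <- lines[-1]
    lineno <- lineno[-1]
  }
  parts <- strsplit(lines, ",")
  if (any(lengths(parts) < 2)) {
    bad <- lineno[which(lengths(parts) < 2)[1]]
    abort_parse("expected two comma-separated columns on line ", bad, " of ", path)
  }
  tm <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
  rr <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  if (anyNA(tm) || anyNA(rr)) {
    bad <- lineno[which(is.na(tm) | is.na(rr))[1]]
    abort_parse("non-numeric value on line ", bad, " of ", path)
  }
  series <- rr_series(rr, label = label)
  if (max(abs(series$time_s - tm)) > 1e-3) {
    abort_validation(
      "csv time column disagrees with the running sum of the intervals ",
      "by more than 1 ms"
    )
  }
  series
}

#' Write an RR-interval series to disk
#'
#' Inverse of [read_rr()]: the round trip reproduces the intervals to full
#' double precision (values are written with 17 significant digits).
#'
#' @param series An [rr_series()].
#' @param path Output path.
#' @param format `"auto"` (by extension), `"txt"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_rr <- function(series, path, format = c("auto", "txt", "csv")) {
  series <- as_rr_series(series)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "txt"
  }
  num <- function(x) formatC(x, digits = 17, format = "g")
  if (format == "txt") {
    writeLines(num(series$rr_ms), path)
  } else {
    writeLines(
      c("time_s,rr_ms", paste(num(series$time_s), num(series$rr_ms), sep = ",")),
      path
    )
  }
  invisible(path)
}

#' Specify a gap (run of missing beats) in an RR series
#'
#' A gap models a run of artifact-corrupted intervals to be discarded and
#' refilled. Gaps are 1-based and cover beats `start, ..., start + length - 1`.
#' `length = 0` is the degenerate no-gap case.
#'
#' @param start 1-based index of the first missing beat.
#' @param length Number of missing beats (>= 0).
#' @return A list of class `gap_spec`.
#' @seealso [middle_gap()] for the centred-gap convention of the evaluation
#'   protocol.
#' @export
gap_spec <- function(start, length) {
  start <- as.integer(start)
  length <- as.integer(length)
  if (is.na(start) || start < 1) abort_validation("gap `start` must be >= 1")
  if (is.na(length) || length < 0) abort_validation("gap `length` must be >= 0")
  structure(list(start = start, length = length), class = "gap_spec")
}

#' @export
print.gap_spec <- function(x, ...) {
  cat(sprintf("<gap_spec> beats %d..%d (length %d)\n",
              x$start, x$start + x$length - 1L, x$length))
  invisible(x)
}

#' Start index of a gap centred in a test window
#'
#' The evaluation protocol introduces the gap "in the middle" of the test
#' window. For a window of `test_length` beats and a gap of `gap_length`
#' beats this is defined, once and for all, as
#' `floor((test_length - gap_length) / 2) + 1` (1-based), i.e. start 121 for
#' the default 250-beat window with a 10-beat gap.
#'
#' @param test_length Number of beats in the test window.
#' @param gap_length Number of beats in the gap.
#' @return 1-based start index within the window.
#' @export
middle_gap <- function(test_length, gap_length) {
  as.integer(floor((test_length - gap_length) / 2) + 1L)
}

check_gap <- function(series, gap, n = nrow(series)) {
  if (!inherits(gap, "gap_spec")) abort_validation("`gap` must be a gap_spec")
  if (gap$length > 0 && gap$start + gap$length - 1L > n) {
    abort_validation(
      "gap beats ", gap$start, "..", gap$start + gap$length - 1L,
      " fall outside the series (length ", n, ")"
    )
  }
  if (gap$length == 0 && gap$start > n + 1L) {
    abort_validation("gap start ", gap$start, " outside series of length ", n)
  }
  invisible(gap)
}

gap_idx <- function(gap) {
  if (gap$length == 0) integer() else seq(gap$start, gap$start + gap$length - 1L)
}

#' Introduce a gap and keep the ground truth
#'
#' Flags the gap beats as unobserved (their `rr_ms` set to `NA`, with an
#' explicit `observed` column rather than sentinel values) and returns the
#' removed values so that correction error can be computed later.
#' Re-inserting `truth` at the gap reproduces the input exactly.
#'
#' @param series An [rr_series()].
#' @param gap A [gap_spec()].
#' @return A list with `series` (tibble with `observed` logical column and
#'   `rr_ms` set to `NA` in the gap) and `truth` (numeric vector of the
#'   removed interval values, length `gap$length`).
#' @export
apply_gap <- function(series, gap) {
  series <- as_rr_series(series)
  check_gap(series, gap)
  idx <- gap_idx(gap)
  truth <- series$rr_ms[idx]
  out <- series
  out$observed <- TRUE
  out$observed[idx] <- FALSE
  out$rr_ms[idx] <- NA_real_
  list(series = out, truth = truth)
}

#' Result of filling (or deleting) a gap
#'
#' Container returned by every corrector: the corrected series, the values
#' inserted into the gap, and the method/configuration provenance. For every
#' filler except deletion the non-gap beats are bit-identical to the input.
#'
#' @param filled The corrected [rr_series()].
#' @param predicted Numeric vector of the inserted gap values (ms); empty for
#'   deletion.
#' @param method Method identifier string.
#' @param gap The [gap_spec()] that was corrected.
#' @param config Optional hyperparameter bundle used.
#' @return A list of class `rr_fill`.
#' @keywords internal
new_rr_fill <- function(filled, predicted, method, gap, config = NULL) {
  structure(
    list(
      filled = filled, predicted = as.numeric(predicted),
      method = method, gap = gap, config = config
    ),
    class = "rr_fill"
  )
}

#' @export
print.rr_fill <- function(x, ...) {
  cat(sprintf(
    "<rr_fill> method '%s', gap beats %d..%d, %d values inserted\n",
    x$method, x$gap$start, x$gap$start + x$gap$length - 1L,
    length(x$predicted)
  ))
  invisible(x)
}

#' @describeIn new_rr_fill Tidy the inserted values: one row per gap beat with
#'   the predicted interval.
#' @param x An `rr_fill` object.
#' @param ... Unused.
#' @export
tidy.rr_fill <- function(x, ...) {
  tibble::tibble(
    beat = gap_idx(x$gap),
    rr_ms = if (length(x$predicted)) x$predicted else numeric()
  )
}

# --- condition helpers -----------------------------------------------------

abort_validation <- function(...) {
  rlang::abort(paste0(...), class = c("hrvfill_validation_error", "hrvfill_error"))
}

abort_parse <- function(...) {
  rlang::abort(paste0(...), class = c("hrvfill_parse_error", "hrvfill_error"))
}

abort_fit <- function(..., config = NULL) {
  rlang::abort(
    paste0(...),
    class = c("hrvfill_fit_error", "hrvfill_error"),
    config = config
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
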