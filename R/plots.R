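#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an RR series as a tachogram
#'
#' @param object An [rr_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rr_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$rr_ms)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "time (s)", y = "RR interval (ms)",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' Plot a gap correction in context
#'
#' Shows the corrected series around the gap, with the inserted values
#' highlighted.
#'
#' @param object An `rr_fill`.
#' @param context Beats shown on each side of the gap (default 40).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rr_fill <- function(object, context = 40, ...) {
  gap <- object$gap
  filled <- object$filled
  lo <- max(1L, gap$start - context)
  hi <- min(nrow(filled), gap$start + gap$length - 1L + context)
  df <- filled[lo:hi, ]
  df$inserted <- df$beat %in% gap_idx(gap)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beat, y = .data$rr_ms)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$inserted), size = 1.6) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey30", `TRUE` = "firebrick"),
      labels = c(`FALSE` = "observed", `TRUE` = "inserted"), name = NULL
    ) +
    ggplot2::labs(x = "beat", y = "RR interval (ms)",
                  title = paste0("gap filled by '", object$method, "'")) +
    ggplot2::theme_minimal()
}

#' Plot a training-size sweep
#'
#' Mean LF and HF relative error as a function of the number of SVR
#' training samples.
#'
#' @param object An `hrv_sweep` from [training_size_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hrv_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), c("lf", "hf"),
                              names_to = "band", values_to = "error")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_train, y = .data$error,
                                     colour = toupper(.data$band))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "training samples", y = "mean relative error (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the criterion landscape of a grid search
#'
#' Configurations sorted by the selection criterion (mean LF + HF error),
#' with the winner highlighted.
#'
#' @param object An `hrv_grid_search`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hrv_grid_search <- function(object, ...) {
  res <- object$results
  res <- res[order(res$criterion), ]
  res$rank <- seq_len(nrow(res))
  res$best <- res$rank == 1 & res$n_failed == 0
  ggplot2::ggplot(res, ggplot2::aes(x = .data$rank, y = .data$criterion)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$best), size = 1.4,
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "configuration (sorted)",
                  y = "mean LF + HF error (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
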