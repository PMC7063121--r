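# ggplot2 displays for sessions and cohort results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the channels of a session
#'
#' Facetted traces of each channel (downsampled for display).
#'
#' @param object an `ortho_session`.
#' @param channels channels to show (default all but sync).
#' @param max_points per-channel point budget.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ortho_session <- function(object, channels = NULL,
                                   max_points = 2000, ...) {
  ch <- object$channels
  if (!"t0" %in% names(ch)) ch$t0 <- 0
  if (is.null(channels)) channels <- setdiff(ch$channel, "sync")
  rows <- which(ch$channel %in% channels)
  df <- dplyr::bind_rows(lapply(rows, function(j) {
    x <- ch$samples[[j]]
    step <- max(1L, floor(length(x) / max_points))
    i <- seq(1L, length(x), by = step)
    tibble::tibble(channel = paste0(ch$channel[j], " [", ch$units[j], "]"),
                   t = ch$t0[j] + (i - 1) / ch$fs[j], value = x[i])
  }))
  ggplot2::ggplot(df, ggplot2::aes(t, value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("participant %s, %s, repeat %s",
                                  object$participant, object$maneuver,
                                  object$rep_idx)) +
    ggplot2::theme_minimal()
}

#' Median/IQR bars of signal-MAP correlations
#'
#' @param summary the `correlation_summary` tibble of an `ortho_report`.
#' @return a ggplot (bars = median, error bars = IQR).
#' @export
plot_signal_correlations <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(signal, median, fill = signal)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = q1, ymax = q3),
                           width = 0.25) +
    ggplot2::facet_wrap(~maneuver) +
    ggplot2::labs(x = NULL, y = "correlation with MAP (Pearson r)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Reliability (ICC) bars per maneuver and quantity
#'
#' @param reliability the `reliability` tibble of an `ortho_report`.
#' @return a ggplot with the qualitative band thresholds drawn.
#' @export
plot_reliability <- function(reliability) {
  ggplot2::ggplot(reliability,
                  ggplot2::aes(quantity, icc, fill = band)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(0.40, 0.60, 0.75),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::facet_wrap(~maneuver) +
    ggplot2::labs(x = NULL, y = "ICC(A,1)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
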