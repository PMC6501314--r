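## ggplot2 visualisations for traces, annotated spectra and frequency
## results.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_segment geom_errorbar labs theme_minimal facet_wrap
NULL

#' Plot an electropherogram trace
#'
#' @param object A [gax_trace()].
#' @param peaks Optional [detect_peaks()] table to mark apexes.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.gax_trace <- function(object, peaks = NULL, ...) {
  p <- ggplot(object, aes(x = .data$time_s, y = .data$rfu)) +
    geom_line(linewidth = 0.3) +
    labs(x = "migration time (s)", y = "RFU",
         title = attr(object, "channel")) +
    theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + geom_point(data = peaks,
                        aes(x = .data$apex_time_s, y = .data$height),
                        colour = "red", shape = 17, inherit.aes = FALSE)
  }
  p
}

#' Plot an annotated fragment spectrum
#'
#' Stem plot of the observed peaks with matched ions coloured by family.
#'
#' @param object A [annotate_spectrum()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.gax_annotation <- function(object, ...) {
  obs <- dplyr::bind_rows(
    dplyr::mutate(object$matches, status = .data$family),
    dplyr::mutate(object$unmatched, observed_mz = .data$mz,
                  status = "unmatched"))
  ggplot(obs, aes(x = .data$observed_mz, xend = .data$observed_mz,
                  y = 0, yend = .data$intensity, colour = .data$status)) +
    geom_segment(linewidth = 0.6) +
    labs(x = "m/z", y = "intensity", colour = "ion family",
         title = sprintf("candidate %s", to_faure(object$struct))) +
    theme_minimal()
}

#' Plot substitution frequencies
#'
#' @param object A [substitution_frequency()] result or a
#'   [run_compare()] comparison (bars with replicate mean +- SD).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.gax_freq <- function(object, ...) {
  ggplot(object, aes(x = .data$class, y = .data$frequency_pct)) +
    geom_col(fill = "grey35") +
    labs(x = NULL, y = "substitution frequency (%)") +
    theme_minimal()
}

#' @rdname autoplot.gax_freq
#' @exportS3Method ggplot2::autoplot
autoplot.gax_comparison <- function(object, ...) {
  ggplot(object$summary, aes(x = .data$class, y = .data$mean_pct)) +
    geom_col(fill = "grey35") +
    geom_errorbar(aes(ymin = .data$mean_pct - .data$sd_pct,
                      ymax = .data$mean_pct + .data$sd_pct), width = 0.2) +
    labs(x = NULL, y = "substitution frequency (%)",
         caption = "error bars: mean +- SD across replicates") +
    theme_minimal()
}
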