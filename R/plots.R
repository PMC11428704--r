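#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result
#' types: waveforms as time traces, WSS series as arc-length/time
#' magnitude maps, index maps as per-index profiles along the wall, and
#' convergence reports as change-vs-cells curves.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name hemoflow-autoplot
NULL

#' @rdname hemoflow-autoplot
#' @export
autoplot.waveform <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(colour = "#b2182b") +
    ggplot2::labs(x = "time (s)", y = wf_unit(object)) +
    ggplot2::theme_minimal()
}

#' @rdname hemoflow-autoplot
#' @export
autoplot.wss_series <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      wss_mag = sqrt(.data$wss_x^2 + .data$wss_y^2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s,
                                   y = .data$arc_length_m * 1000,
                                   fill = .data$wss_mag)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "|WSS| (Pa)") +
    ggplot2::labs(x = "time (s)", y = "arc length (mm)") +
    ggplot2::theme_minimal()
}

#' @rdname hemoflow-autoplot
#' @export
autoplot.index_maps <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("arc_length_m", "tawss", "osi", "rrt",
                                  "ecap")],
    cols = c("tawss", "osi", "rrt", "ecap"),
    names_to = "index", values_to = "value")
  df$index <- factor(toupper(df$index),
                     levels = c("TAWSS", "OSI", "RRT", "ECAP"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arc_length_m * 1000,
                                   y = .data$value)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "arc length (mm)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Compare two pressure waveforms (e.g. true vs false lumen)
#'
#' Overlays a test and a reference waveform and annotates the systolic
#' amplification and peak lead from [systolic_metrics()].
#'
#' @param test,reference [waveform()]s with the same unit and period.
#' @return A ggplot object.
#' @export
plot_waveform_pair <- function(test, reference) {
  sm <- systolic_metrics(test, reference)
  df <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(test), trace = "test"),
    dplyr::mutate(tibble::as_tibble(reference), trace = "reference"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value,
                                   colour = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(test = "#b2182b",
                                            reference = "#2166ac")) +
    ggplot2::labs(x = "time (s)", y = wf_unit(reference),
                  subtitle = sprintf("amplification %.1f%%, peak lead %.3f s",
                                     sm$amplification, sm$peak_lead)) +
    ggplot2::theme_minimal()
}
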