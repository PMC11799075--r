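# ggplot2 displays for the result objects.

#' Plot an incident spectrum
#'
#' Step histogram of the primary and scattered rate components.
#'
#' @param object A `gc_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gc_spectrum <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object), c("primary_rate", "scatter_rate"),
    names_to = "component", values_to = "rate")
  long$component <- sub("_rate$", "", long$component)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin_low_keV, y = .data$rate,
                                     colour = .data$component)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Energy (keV)", y = "Incident rate (photons/s/bin)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a dead-time loss time course
#'
#' @param object A `gc_timecourse` from [loss_curve()] or an experiment.
#' @param ... Unused.
#' @return A ggplot of loss (%) against time, one line per configuration
#'   (faceted by detector when present).
#' @export
autoplot.gc_timecourse <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$time_h, y = .data$loss_pct,
                                    colour = .data$config)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Time after administration (h)",
                  y = "Dead-time loss (%)", colour = "filter") +
    ggplot2::theme_minimal()
  if ("detector" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$detector),
                                 labeller = ggplot2::label_both)
  }
  p
}

#' Plot an experiment
#'
#' @param object A `gc_experiment`.
#' @param which `"timecourse"` (default) or `"summary"` (per-configuration
#'   window fraction, apparent dead time and loss at 24 h).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gc_experiment <- function(object,
                                   which = c("timecourse", "summary"), ...) {
  which <- match.arg(which)
  if (which == "timecourse") return(autoplot.gc_timecourse(object$timecourse))
  long <- tidyr::pivot_longer(
    dplyr::select(object$summary, "detector", "filter", "wf_mean",
                  "tau_w_us_mean", "loss_pct_mean"),
    c("wf_mean", "tau_w_us_mean", "loss_pct_mean"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$filter, y = .data$value,
                                     fill = factor(.data$detector))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "detector") +
    ggplot2::theme_minimal()
}
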