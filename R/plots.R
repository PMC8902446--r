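#' Plot a simulated trajectory
#'
#' One line per state coordinate, faceted by block.
#'
#' @param object An `fep_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fep_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"t",
                              names_to = "state", values_to = "value") |>
    dplyr::mutate(block = substr(.data$state, 1, 1))
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value,
                                     colour = .data$state)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~block, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "t", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a path comparison
#'
#' Overlays the true conditional-mode path and the marginal-flow surrogate
#' per external coordinate; if ensemble variances are present, adds a panel
#' with `Var[m~_y(t)]` against the stationary plateau of `Var[m_y(b_t)]`.
#'
#' @param object An `fep_path_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fep_path_comparison <- function(object, ...) {
  if (!is.null(object$variance)) {
    long <- tidyr::pivot_longer(object$variance, -"t",
                                names_to = "series", values_to = "variance")
    return(ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$variance,
                                              colour = .data$series)) +
             ggplot2::geom_line() +
             ggplot2::labs(x = "t", y = "ensemble variance", colour = NULL) +
             ggplot2::theme_minimal())
  }
  abort("single-pair comparisons carry no stored paths; plot the paths directly")
}

#' Plot residual scaling from an epsilon sweep
#'
#' Median residual against coupling strength on log-log axes, one line per
#' metric; the slopes are the empirical residual orders.
#'
#' @param sweep A tibble from [epsilon_sweep()].
#' @param metrics Optional subset of metric names.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, metrics = NULL) {
  d <- dplyr::filter(sweep, .data$epsilon > 0, .data$value > 0)
  if (!is.null(metrics)) d <- dplyr::filter(d, .data$metric %in% metrics)
  med <- d |>
    dplyr::group_by(.data$structure, .data$metric, .data$epsilon) |>
    dplyr::summarise(med = median(.data$value), .groups = "drop")
  ggplot2::ggplot(med, ggplot2::aes(.data$epsilon, .data$med,
                                    colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~structure) +
    ggplot2::labs(x = "coupling strength", y = "median residual",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the bivariate spiral-flow demonstration
#'
#' True flow field (arrows, spiralling into the origin) with the
#' conditional average flow of `y` shown along the blanket axis.
#'
#' @param demo Output of [bivariate_demo()].
#' @return A ggplot object.
#' @export
plot_bivariate_demo <- function(demo) {
  f <- demo$flow_field
  sc <- 0.2 * diff(range(f$y)) / max(sqrt(f$dy^2 + f$db^2))
  ggplot2::ggplot(f, ggplot2::aes(.data$b, .data$y)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$b + sc * .data$db,
                                       yend = .data$y + sc * .data$dy),
                          arrow = ggplot2::arrow(length = ggplot2::unit(0.03, "npc")),
                          linewidth = 0.2, colour = "grey40") +
    ggplot2::geom_line(data = demo$conditional_flow,
                       ggplot2::aes(.data$b, .data$flow_y),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "b", y = "y",
                  title = "true flow (arrows) vs conditional average flow of y (line)") +
    ggplot2::theme_minimal()
}
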