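#' Plot methods
#'
#' `autoplot()` methods give the three standard figures of a screening
#' cost-effectiveness analysis: the cost-effectiveness plane with the
#' efficiency frontier (`crc_cea`), the cost-effectiveness acceptability
#' curve (`crc_psa`), and the tornado diagram of the one-way sensitivity
#' analysis (`crc_dsa`).
#'
#' @param object Result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name plots
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plots
#' @export
autoplot.crc_cea <- function(object, ...) {
  tab <- object$table
  front <- tab[tab$on_frontier, ]
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$effect, y = .data$cost)) +
    ggplot2::geom_line(data = front[order(front$cost), ],
                       colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$on_frontier), size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$strategy),
                       vjust = -0.8, size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey55"),
                                 guide = "none") +
    ggplot2::labs(x = "DALYs averted per person (vs natural history)",
                  y = "Discounted lifetime cost per person (USD)",
                  title = "Cost-effectiveness plane")
}

#' @rdname plots
#' @export
autoplot.crc_psa <- function(object, ...) {
  ggplot2::ggplot(object$ceac,
                  ggplot2::aes(x = .data$wtp, y = .data$fraction,
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$base_wtp, linetype = "dashed") +
    ggplot2::labs(x = "Willingness to pay (USD per DALY averted)",
                  y = "Probability most cost-effective",
                  colour = NULL,
                  title = "Cost-effectiveness acceptability curve")
}

#' @rdname plots
#' @export
autoplot.crc_dsa <- function(object, ...) {
  base <- attr(object, "icer_base")
  tab <- dplyr::mutate(tibble::as_tibble(object),
                       path = factor(.data$path,
                                     levels = rev(.data$path)))
  ggplot2::ggplot(tab) +
    ggplot2::geom_segment(ggplot2::aes(y = .data$path, yend = .data$path,
                                       x = .data$icer_low,
                                       xend = .data$icer_high),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed") +
    ggplot2::labs(x = "ICER (USD per DALY averted)", y = NULL,
                  title = "One-way sensitivity (tornado)")
}

#' Incidence curve of a trace
#'
#' @param trace A `crc_trace`.
#' @param band_width Age-band width in years.
#' @return A ggplot of age-specific incidence per 100,000 person-years.
#' @export
plot_incidence <- function(trace, band_width = 5) {
  s <- incidence_and_stage_summary(trace, band_width)
  ggplot2::ggplot(s$incidence,
                  ggplot2::aes(x = .data$age_band_start,
                               y = .data$rate_per_100k)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Age band", y = "CRC incidence per 100,000 PY")
}
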