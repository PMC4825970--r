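#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a precision regression
#'
#' Interval width against mean node age, one colour and fitted line per
#' dating analysis — the standard visual check that uncertainty grows with
#' node age and shrinks as calibrations are added.
#'
#' @param object A `precision_fit` from [precision_regression()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.precision_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$mean_age, y = .data$width,
                               colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "Mean node age (Ma)", y = "95% interval width (Myr)",
                  colour = "Analysis") +
    ggplot2::theme_minimal()
}

#' Plot a congruence decision report
#'
#' One row per tested hypothesis: the per-analysis 95% divergence-time
#' intervals as segments and the geological/biotic window as a shaded band,
#' coloured by decision.
#'
#' @param object A `congruence_report` from [run_hypothesis_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.congruence_report <- function(object, ...) {
  d <- object$decisions
  d$hypothesis <- paste(d$cladogenetic_event, d$geological_event, sep = " — ")
  long <- tidyr::pivot_longer(
    d, cols = dplyr::matches("^B[123]_(lower|upper)$"),
    names_to = c("label", ".value"), names_pattern = "(B[123])_(lower|upper)")
  ggplot2::ggplot(long) +
    ggplot2::geom_rect(
      data = d,
      ggplot2::aes(xmin = pmin(.data$older_ma, .data$younger_ma),
                   xmax = pmax(.data$older_ma, .data$younger_ma),
                   ymin = as.numeric(factor(.data$hypothesis)) - 0.4,
                   ymax = as.numeric(factor(.data$hypothesis)) + 0.4,
                   fill = .data$decision), alpha = 0.3) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$lower, xend = .data$upper,
                   y = as.numeric(factor(.data$hypothesis)) +
                     0.2 * (match(.data$label, c("B1", "B2", "B3")) - 2),
                   yend = as.numeric(factor(.data$hypothesis)) +
                     0.2 * (match(.data$label, c("B1", "B2", "B3")) - 2),
                   colour = .data$label), linewidth = 1) +
    ggplot2::scale_y_continuous(
      breaks = seq_along(levels(factor(long$hypothesis))),
      labels = levels(factor(long$hypothesis))) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Age (Ma)", y = NULL, colour = "Analysis",
                  fill = "Decision") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 7))
}

#' Plot node-age posteriors against an event window
#'
#' Density of the age samples per analysis label for one clade, with an
#' optional geological window shaded — the per-node view used to judge
#' temporal congruence.
#'
#' @param posterior Tibble `label`, `clade`, `age`.
#' @param clade Clade key to plot (default: first in the table).
#' @param window Optional numeric `c(older, younger)` bounds in Ma.
#' @return A ggplot object.
#' @export
plot_age_posterior <- function(posterior, clade = NULL, window = NULL) {
  if (is.null(clade)) clade <- posterior$clade[1]
  df <- dplyr::filter(posterior, .data$clade == !!clade)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$age, colour = .data$label)) +
    ggplot2::geom_density() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Age (Ma)", y = "Posterior density", colour = "Analysis",
                  title = clade) +
    ggplot2::theme_minimal()
  if (!is.null(window)) {
    p <- p + ggplot2::annotate("rect", xmin = max(window), xmax = min(window),
                               ymin = -Inf, ymax = Inf, alpha = 0.2)
  }
  p
}
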