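#' Plot melting curves
#'
#' Order parameter density `<n_c>/(n + 1)` against temperature, one line per
#' recorded chain length.
#'
#' @param object A `melt_curve` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.melt_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$temp, .data$frac_bound,
                               colour = factor(.data$n))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "temperature  (k_B T / ε)",
                  y = "bound fraction  ⟨n_c⟩ / (n + 1)",
                  colour = "n") +
    ggplot2::theme_minimal()
}

#' Plot a finite-size data collapse
#'
#' Scaled curves `value / N^(m phi)` against `(T - T_m) N^phi` at the
#' fitted parameters; a good fit puts all lengths on one master curve.
#'
#' @param object A `collapse_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.collapse_fit <- function(object, ...) {
  d <- dplyr::mutate(object$data,
                     x = (.data$temp - object$t_m) * .data$N^object$phi,
                     y = .data$value / .data$N^(object$mult * object$phi))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y,
                                  colour = factor(.data$N))) +
    ggplot2::geom_point(size = 1) + ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(
      x = expression((T - T[m]) * N^phi),
      y = if (object$observable == "n_c") expression(n[c] / N^phi)
          else expression(C[c] / N^{2 * phi}),
      colour = "N",
      title = sprintf("T_m = %.4f, phi = %.3f", object$t_m, object$phi)) +
    ggplot2::theme_minimal()
}

#' Plot a bubble-size power-law fit
#'
#' @param object A `powerlaw_fit`.
#' @param ... Unused.
#' @return A ggplot on log-log axes with the fitted line.
#' @export
autoplot.powerlaw_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$size, .data$prob)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(l[b]), y = expression(P(l[b])),
                  title = sprintf("c = %.2f ± %.2f", object$c,
                                  object$se)) +
    ggplot2::theme_minimal()
}

#' Plot the tour-weight sampling diagnostic
#'
#' @param object A `tour_weight_diag`.
#' @param ... Unused.
#' @return A ggplot overlaying `P(ln W)` and `W P(ln W)`.
#' @export
autoplot.tour_weight_diag <- function(object, ...) {
  d <- tidyr::pivot_longer(object$hist, c("p", "wp"), names_to = "which")
  ggplot2::ggplot(d, ggplot2::aes(.data$ln_w, .data$value,
                                  colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_discrete(labels = c(p = "P(ln W)",
                                              wp = "W P(ln W)")) +
    ggplot2::labs(x = "ln W", y = "normalized mass", colour = NULL,
                  title = sprintf("overlap = %.3f", object$overlap)) +
    ggplot2::theme_minimal()
}

#' Plot spanning-probability curves
#'
#' @param curves A tibble from [spanning_curve()].
#' @param p_c Optional vertical reference line.
#' @return A ggplot; the crossing of the per-`L` curves estimates the
#'   percolation threshold.
#' @export
plot_spanning_curves <- function(curves, p_c = NULL) {
  g <- ggplot2::ggplot(curves,
                       ggplot2::aes(.data$p, .data$spanning_frac,
                                    colour = factor(.data$L))) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$spanning_frac - .data$se,
      ymax = .data$spanning_frac + .data$se), size = 0.2) +
    ggplot2::labs(x = "retention probability p", y = "spanning fraction",
                  colour = "L") +
    ggplot2::theme_minimal()
  if (!is.null(p_c))
    g <- g + ggplot2::geom_vline(xintercept = p_c, linetype = 2)
  g
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
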