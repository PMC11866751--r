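#' Tidy a collapse fit
#'
#' @param x A `collapse_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @export
tidy.collapse_fit <- function(x, ...) {
  tibble(term = c("t_m", "phi"),
         estimate = c(x$t_m, x$phi),
         std.error = unname(x$se))
}

#' @rdname tidy.collapse_fit
#' @export
glance.collapse_fit <- function(x, ...) {
  tibble(t_m = x$t_m, phi = x$phi, quality = x$quality,
         observable = x$observable,
         n_curves = length(unique(x$data$N)), n_points = nrow(x$data),
         n_overlap = x$n_overlap, converged = x$convergence == 0)
}

#' Tidy a bubble-exponent fit
#'
#' @param x A `powerlaw_fit`.
#' @param ... Unused.
#' @return One row: `term = "c"`, `estimate`, `std.error`.
#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble(term = "c", estimate = x$c, std.error = x$se)
}

#' @rdname tidy.powerlaw_fit
#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble(c = x$c, se = x$se, window_min = x$window[1],
         window_max = x$window[2], n_bins = x$n_bins)
}

#' Tidy a phase-line fit
#'
#' @param x A `phase_line_fit`.
#' @param ... Unused.
#' @return One row per parameter (`c1`, `c2`, `alpha`).
#' @export
tidy.phase_line_fit <- function(x, ...) {
  tibble(term = c("c1", "c2", "alpha"),
         estimate = c(x$c1, x$c2, x$alpha),
         std.error = c(x$c1_se, x$c2_se, x$alpha_se))
}

#' @rdname tidy.phase_line_fit
#' @export
glance.phase_line_fit <- function(x, ...) {
  tibble(c1 = x$c1, c2 = x$c2, alpha = x$alpha, kappa = x$kappa,
         n_points = nrow(x$residuals))
}
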