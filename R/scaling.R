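#' Finite-size data collapse for the melting point and crossover exponent
#'
#' Near the transition the order parameter obeys
#' `n_c / N^phi = h((T - T_m) N^phi)` and its fluctuation
#' `C_c / N^(2 phi) = g((T - T_m) N^phi)`: curves for different chain
#' lengths fall onto one master curve at the true `(T_m, phi)`.  The fit
#' minimizes a collapse-quality objective: the mean squared deviation of
#' each scaled point from the linear interpolation of the other curves at
#' the same scaled abscissa, normalized by the overall variance (so the
#' objective is invariant under curve relabeling and common rescaling of y).
#' Optimization is Nelder-Mead from the best point of a coarse grid.
#'
#' @param data A tibble with columns `N`, `temp`, `value` (the observable:
#'   `<n_c>` for `observable = "n_c"`, `C_c` for `"C_c"`); at least two
#'   distinct `N` with overlapping scaled-temperature ranges.
#' @param observable Which scaling form to use: `"n_c"` scales the ordinate
#'   by `N^phi`, `"C_c"` by `N^(2 phi)`.
#' @param t_m,phi Optional starting values; by default a coarse grid over
#'   the data's temperature range and `phi` in `[0.3, 1.4]` picks the start.
#' @return An object of class `collapse_fit`: list with `t_m`, `phi`,
#'   `quality` (dimensionless; small is good), `se` (rough standard errors
#'   from the curvature of the objective), `observable`, `data`,
#'   `n_overlap` (points with cross-curve comparisons at the optimum).
#' @examples
#' syn <- synthetic_collapse_curves(t_m = 0.75, phi = 1,
#'                                  N = c(50, 100, 200),
#'                                  temps = seq(0.70, 0.80, by = 0.005))
#' fit <- fit_collapse(syn, "n_c")
#' glance(fit)
#' @export
fit_collapse <- function(data, observable = c("n_c", "C_c"),
                         t_m = NULL, phi = NULL) {
  observable <- match.arg(observable)
  stopifnot(all(c("N", "temp", "value") %in% names(data)))
  data <- dplyr::filter(data, is.finite(.data$value))
  Ns <- sort(unique(data$N))
  if (length(Ns) < 2) abort("need curves for at least two chain lengths")
  mult <- if (observable == "n_c") 1 else 2

  obj <- function(par) collapse_quality(data, par[1], par[2], mult)$q

  if (is.null(t_m) || is.null(phi)) {
    grid <- tidyr::expand_grid(
      t_m = seq(min(data$temp), max(data$temp), length.out = 15),
      phi = seq(0.3, 1.4, by = 0.1))
    qs <- purrr::map2_dbl(grid$t_m, grid$phi, ~ obj(c(.x, .y)))
    if (all(!is.finite(qs)))
      abort("no overlapping scaled-temperature windows; collapse fit refused")
    best <- which.min(qs)
    start <- c(grid$t_m[best], grid$phi[best])
  } else start <- c(t_m, phi)

  opt <- optim(start, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-10, maxit = 2000))
  final <- collapse_quality(data, opt$par[1], opt$par[2], mult)
  if (final$n_overlap == 0)
    abort("no overlapping scaled-temperature windows; collapse fit refused")

  se <- tryCatch({
    h <- numeric_hessian(obj, opt$par)
    v <- tryCatch(diag(solve(h)) * 2 * opt$value, error = function(e) rep(NA, 2))
    sqrt(pmax(v, 0))
  }, error = function(e) c(NA_real_, NA_real_))

  out <- list(t_m = opt$par[1], phi = opt$par[2], quality = opt$value,
              se = stats::setNames(se, c("t_m", "phi")),
              observable = observable, mult = mult, data = data,
              n_overlap = final$n_overlap, convergence = opt$convergence)
  class(out) <- "collapse_fit"
  out
}

# collapse quality: for each point, residual to the mean of the other
# curves' linear interpolations at its scaled abscissa
collapse_quality <- function(data, t_m, phi, mult) {
  if (!is.finite(t_m) || !is.finite(phi) || phi <= 0 || phi > 2)
    return(list(q = Inf, n_overlap = 0))
  d <- dplyr::mutate(data,
                     x = (.data$temp - t_m) * .data$N^phi,
                     y = .data$value / .data$N^(mult * phi))
  curves <- split(d[c("x", "y")], d$N)
  curves <- lapply(curves, function(cu) cu[order(cu$x), ])
  resid <- c()
  for (i in seq_along(curves)) {
    ci <- curves[[i]]
    preds <- matrix(NA_real_, nrow(ci), length(curves))
    for (j in seq_along(curves)) {
      if (i == j) next
      cj <- curves[[j]]
      if (nrow(cj) < 2) next
      preds[, j] <- approx(cj$x, cj$y, xout = ci$x, rule = 1, ties = mean)$y
    }
    pm <- rowMeans(preds, na.rm = TRUE)
    ok <- is.finite(pm)
    resid <- c(resid, ci$y[ok] - pm[ok])
  }
  if (length(resid) == 0) return(list(q = Inf, n_overlap = 0))
  list(q = mean(resid^2) / max(var(d$y), .Machine$double.eps),
       n_overlap = length(resid))
}

numeric_hessian <- function(f, x, eps = 1e-4) {
  k <- length(x)
  h <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) for (j in i:k) {
    ei <- ej <- numeric(k); ei[i] <- eps; ej[j] <- eps
    h[i, j] <- h[j, i] <-
      (f(x + ei + ej) - f(x + ei) - f(x + ej) + f0) / eps^2
  }
  h
}

#' @export
print.collapse_fit <- function(x, ...) {
  cat(sprintf("<collapse_fit> %s: T_m = %.4f, phi = %.3f (quality %.3g, %d overlapping points)\n",
              x$observable, x$t_m, x$phi, x$quality, x$n_overlap))
  invisible(x)
}

#' Power-law fit of the bubble-size distribution
#'
#' At the melting point the bubble sizes follow `P(l_b) ~ l_b^(-c)` with
#' reunion exponent `c` (`c >= 2` for first-order melting, `1 < c < 2` for
#' continuous).  `c` is minus the least-squares slope of `log P` against
#' `log l_b` over an intermediate window, by default sizes 20-100, where
#' the power law holds free of small-size and finite-chain corrections.
#'
#' @param dist A tibble with columns `size` and `prob` (e.g. the
#'   `bubble_dist` entry of a [melt_curve()] row).
#' @param window Fit window `c(min, max)` in bubble sizes.
#' @return An object of class `powerlaw_fit`: list with `c` (exponent
#'   magnitude), `se`, `window`, `n_bins`, `data` (points used).
#' @export
fit_bubble_exponent <- function(dist, window = c(20, 100)) {
  use <- dplyr::filter(dist, .data$size >= window[1], .data$size <= window[2],
                       .data$prob > 0)
  if (nrow(use) < 5)
    abort(sprintf("only %d populated bins in [%g, %g]; power-law fit refused",
                  nrow(use), window[1], window[2]))
  fit <- lm(log(prob) ~ log(size), data = use)
  out <- list(c = -unname(coef(fit)[2]),
              se = unname(sqrt(diag(vcov(fit)))[2]),
              window = window, n_bins = nrow(use), data = use)
  class(out) <- "powerlaw_fit"
  out
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> c = %.3f +- %.3f over sizes [%g, %g] (%d bins)\n",
              x$c, x$se, x$window[1], x$window[2], x$n_bins))
  invisible(x)
}

#' Peak of each fluctuation curve vs inverse system size
#'
#' Locates the interior maximum of `C_c(T)` for each chain length by
#' quadratic interpolation through the three samples around the grid
#' maximum, and emits the peak series against `1/N` (the divergence of the
#' peak with `N` distinguishes weak from strong disorder).
#'
#' @param curves A tibble with columns `N`, `temp`, `value` (`C_c`).
#' @return A tibble per `N`: `t_peak`, `value_peak`, `inv_N`, `no_peak`
#'   (`TRUE` when the curve is monotone / the maximum sits on the grid
#'   boundary, in which case the peak columns are `NA`).
#' @export
cc_peak_scaling <- function(curves) {
  dplyr::group_modify(dplyr::group_by(curves, .data$N), function(d, key) {
    d <- dplyr::arrange(d, .data$temp)
    i <- which.max(d$value)
    if (i == 1 || i == nrow(d) || all(diff(d$value) >= 0) ||
        all(diff(d$value) <= 0))
      return(tibble(t_peak = NA_real_, value_peak = NA_real_, no_peak = TRUE))
    # quadratic through the three samples around the maximum
    xs <- d$temp[(i - 1):(i + 1)]; ys <- d$value[(i - 1):(i + 1)]
    qf <- lm(ys ~ xs + I(xs^2))
    b <- coef(qf)
    t_pk <- -b[2] / (2 * b[3])
    tibble(t_peak = unname(t_pk),
           value_peak = unname(b[1] + b[2] * t_pk + b[3] * t_pk^2),
           no_peak = FALSE)
  }) |>
    dplyr::ungroup() |>
    dplyr::mutate(inv_N = 1 / .data$N)
}

#' Fit the melting phase line T_m(p)
#'
#' Two descriptions of how the melting temperature varies with medium
#' dilution are fitted: globally, `T_m(p) = 1 / ln(c1 p + c2)` -- motivated
#' by the observed linear variation of `exp(1/T_m)` with `p`, so `(c1, c2)`
#' come from an ordinary linear fit of `exp(1/T_m)` against `p` -- and, on
#' the weak-disorder window `p` in `[0.6, 1]`, a power law
#' `T_m ~ p^(-alpha)` fitted on log-log axes.  The power-law residuals over
#' the full range diagnose where the weak-disorder description breaks down.
#'
#' @param points A tibble with columns `p` and `t_m` (at least 3 points;
#'   at least 3 inside `[0.6, 1]` for the power-law part, else `alpha` is
#'   `NA`).
#' @param power_window Window for the power-law fit.
#' @return An object of class `phase_line_fit`: list with `c1`, `c2` (and
#'   their `se`), `alpha`, `alpha_se`, `power_window`, `residuals` (per
#'   point: phase-line and power-law residuals), and a condition-number
#'   diagnostic `kappa`.
#' @export
fit_phase_line <- function(points, power_window = c(0.6, 1)) {
  stopifnot(all(c("p", "t_m") %in% names(points)))
  if (nrow(points) < 3) abort("need at least 3 (p, T_m) points")
  lin <- lm(exp(1 / t_m) ~ p, data = points)
  cf <- coef(lin); se <- sqrt(diag(vcov(lin)))
  kappa <- kappa(stats::model.matrix(lin))
  if (kappa > 1e8) warn("ill-conditioned phase-line fit")

  inwin <- points$p >= power_window[1] & points$p <= power_window[2]
  alpha <- alpha_se <- NA_real_
  if (sum(inwin) >= 3) {
    pw <- lm(log(t_m) ~ log(p), data = points[inwin, ])
    alpha <- -unname(coef(pw)[2])
    alpha_se <- unname(sqrt(diag(vcov(pw)))[2])
    pred_pow <- exp(predict(pw, newdata = points))
  } else pred_pow <- rep(NA_real_, nrow(points))

  resid <- tibble(
    p = points$p, t_m = points$t_m,
    phase_line = points$t_m - 1 / log(cf[2] * points$p + cf[1]),
    power_law = points$t_m - pred_pow)
  out <- list(c1 = unname(cf[2]), c2 = unname(cf[1]),
              c1_se = unname(se[2]), c2_se = unname(se[1]),
              alpha = alpha, alpha_se = alpha_se,
              power_window = power_window, residuals = resid, kappa = kappa)
  class(out) <- "phase_line_fit"
  out
}

#' @export
print.phase_line_fit <- function(x, ...) {
  cat(sprintf("<phase_line_fit> T_m(p) = 1/ln(c1 p + c2): c1 = %.3f +- %.3f, c2 = %.3f +- %.3f\n",
              x$c1, x$c1_se, x$c2, x$c2_se))
  cat(sprintf("  weak-disorder power law over [%.2f, %.2f]: alpha = %.3f +- %.3f\n",
              x$power_window[1], x$power_window[2], x$alpha, x$alpha_se))
  invisible(x)
}

#' Melting-point estimate from the order parameter's inflection
#'
#' Fallback estimator for strongly disordered media, where fluctuation
#' cumulants converge too slowly: `T_m` is taken as the temperature of
#' steepest descent of a smoothing spline through `<n_c>(T)`.  Less
#' accurate than the data collapse; use when only the first moment is
#' reliable.
#'
#' @param curve A tibble with columns `temp` and `mean_nc` (single `N`).
#' @return A list with `t_m` and the spline's derivative extremum value.
#' @export
estimate_tm_inflection <- function(curve) {
  d <- dplyr::arrange(dplyr::filter(curve, is.finite(.data$mean_nc)),
                      .data$temp)
  if (nrow(d) < 5) abort("need at least 5 temperature points")
  sp <- stats::smooth.spline(d$temp, d$mean_nc)
  grid <- seq(min(d$temp), max(d$temp), length.out = 500)
  deriv <- stats::predict(sp, grid, deriv = 1)$y
  i <- which.min(deriv)  # steepest descent of the order parameter
  list(t_m = grid[i], slope = deriv[i])
}
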