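#' Build a melting-experiment configuration
#'
#' Collects every parameter of an end-to-end scan -- media dilution values,
#' chain lengths, temperature grid, sampling and disorder-replication
#' budgets, seeds, bias depth -- into one validated object so a run is
#' exactly reproducible from its manifest.
#'
#' @param p Retention probabilities to scan.
#' @param L Box size (odd).
#' @param N Chain lengths.
#' @param temps Strictly increasing temperature grid.
#' @param tours Tours per (realization, temperature).
#' @param realizations Disorder realizations per `p` (1 is forced at
#'   `p = 1`, where there is no disorder).
#' @param seed Master seed.
#' @param bias_depth Pyramid look-ahead depth (0 = off).
#' @param method Leath growth order.
#' @param lengths Lengths at which observables are recorded; defaults to
#'   all of `N` harvested from the largest-`N` run.
#' @return A `melt_config` list.
#' @export
melting_config <- function(p = 1, L = 99L, N = c(50L, 100L, 200L),
                           temps = seq(0.70, 0.80, by = 0.01),
                           tours = 10000L, realizations = 1L, seed = 1L,
                           bias_depth = 0L,
                           method = c("depth_first", "breadth_first"),
                           lengths = NULL) {
  method <- match.arg(method)
  if (any(diff(temps) <= 0)) abort("`temps` must be strictly increasing")
  if (L %% 2 != 1) abort("`L` must be odd")
  if (tours < 1 || realizations < 1 || any(N < 1)) abort("counts must be >= 1")
  structure(list(p = p, L = as.integer(L), N = as.integer(sort(N)),
                 temps = as.numeric(temps), tours = as.integer(tours),
                 realizations = as.integer(realizations),
                 seed = as.integer(seed), bias_depth = as.integer(bias_depth),
                 method = method,
                 lengths = if (is.null(lengths)) as.integer(sort(N))
                           else as.integer(sort(lengths))),
            class = "melt_config")
}

#' Run a full melting experiment
#'
#' For each `p`: generates spanning disorder realizations (full lattice at
#' `p = 1`), runs the PERM temperature scan on each at the largest chain
#' length (observables at all requested lengths are harvested from the same
#' runs), forms annealed and quenched disorder averages, and fits the
#' order-parameter data collapse.  Everything is keyed by the manifest so a
#' rerun with the same config is bit-identical.
#'
#' @param config A [melting_config()].
#' @return A list of class `melt_experiment`: `config`, `ensembles` (one
#'   `disorder_ensemble` per `p`), `averages` (tibble over `p`, mode,
#'   temp, n), `collapse` (one `collapse_fit` per `p`, from the annealed
#'   `<n_c>` curves), and `manifest`.
#' @export
run_melting_experiment <- function(config) {
  stopifnot(inherits(config, "melt_config"))
  Nmax <- max(config$N)
  ensembles <- list()
  averages <- list()
  fits <- list()
  for (i in seq_along(config$p)) {
    p <- config$p[i]
    ens <- run_disorder_ensemble(
      p = p, L = config$L, N = Nmax, temps = config$temps,
      realizations = if (p >= 1) 1L else config$realizations,
      tours = config$tours, seed = derive_seed(config$seed, 524287L * i),
      bias_depth = config$bias_depth, lengths = config$lengths,
      method = config$method)
    avg <- disorder_average(ens)
    avg$p <- p
    ensembles[[as.character(p)]] <- ens
    averages[[i]] <- avg
    cdat <- avg |>
      dplyr::filter(.data$mode == "annealed", .data$n %in% config$N) |>
      dplyr::transmute(N = .data$n, temp = .data$temp, value = .data$mean_nc)
    fits[[as.character(p)]] <- tryCatch(fit_collapse(cdat, "n_c"),
                                        error = function(e) e)
  }
  out <- list(config = config, ensembles = ensembles,
              averages = dplyr::bind_rows(averages), collapse = fits,
              manifest = manifest(config))
  class(out) <- "melt_experiment"
  out
}

manifest <- function(config) {
  c(unclass(config),
    list(package_version = as.character(utils::packageVersion("crowdmelt"))))
}

#' @export
print.melt_experiment <- function(x, ...) {
  cat(sprintf("<melt_experiment> p = {%s}, N = {%s}, %d temps, %d tours\n",
              paste(x$config$p, collapse = ", "),
              paste(x$config$N, collapse = ", "),
              length(x$config$temps), x$config$tours))
  for (p in names(x$collapse)) {
    f <- x$collapse[[p]]
    if (inherits(f, "collapse_fit"))
      cat(sprintf("  p = %s: T_m = %.4f, phi = %.3f\n", p, f$t_m, f$phi))
    else cat(sprintf("  p = %s: collapse fit failed (%s)\n", p,
                     conditionMessage(f)))
  }
  invisible(x)
}

#' Production-scale long-run configurations
#'
#' Production-scale settings for the results that are far beyond a desktop
#' run: the strong-disorder bubble exponent, the `p = 0.8`
#' disorder-averaged collapse, and the phase line over the weak-disorder
#' window.  These need `L = 599` boxes, chains of `N = 500`, and large
#' disorder ensembles; they are shipped as configurations, not run by the
#' test suite.
#'
#' @return A named list of [melting_config()] objects.
#' @export
long_run_configs <- function() {
  list(
    strong_disorder_bubbles = melting_config(
      p = 0.312, L = 599L, N = 500L,
      temps = seq(1.05, 1.25, by = 0.01), tours = 10000L,
      realizations = 10000L, bias_depth = 3L),
    weak_disorder_collapse = melting_config(
      p = 0.8, L = 599L, N = c(200L, 300L, 400L, 500L),
      temps = seq(0.86, 0.93, by = 0.005), tours = 10000L,
      realizations = 1000L, bias_depth = 3L),
    phase_line = melting_config(
      p = c(0.6, 0.7, 0.8, 0.9, 1.0), L = 599L,
      N = c(200L, 300L, 400L, 500L),
      temps = seq(0.70, 1.00, by = 0.005), tours = 10000L,
      realizations = 1000L, bias_depth = 3L),
    contact_distribution_shape = melting_config(
      p = 0.5, L = 599L, N = 500L,
      temps = seq(0.95, 1.05, by = 0.005), tours = 10000L,
      realizations = 1000L, bias_depth = 3L)
  )
}
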