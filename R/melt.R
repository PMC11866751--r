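#' Sample the dual-strand DNA with PERM over a temperature grid
#'
#' Grows the two mutually avoiding strands from the pinned origin with the
#' pruned-enriched Rosenbluth method, one independent run per temperature,
#' and returns weighted thermal observables at the requested chain lengths.
#' A base-pair contact (equal-index co-occupation of a site) carries energy
#' `-1` in units of the pairing energy, so the Boltzmann factor per contact
#' is `exp(1 / T)` (`epsilon = k_B = 1`).
#'
#' Because the running partition-sum estimate exists at every intermediate
#' length, a single run at the largest `N` yields curves for all shorter
#' lengths at no extra cost; request them via `lengths`.
#'
#' @param lattice A `leath_lattice` (use [full_lattice()] or `NULL` for the
#'   undiluted case).  If `NULL`, a full lattice of size `L` is built.
#' @param N Target number of base pairs (strands carry `N + 1` monomers
#'   including the pinned origin pair).
#' @param temps Numeric vector of temperatures.
#' @param tours Started tours per temperature; the partition sum is the mean
#'   tour weight `Z_n = <W_n>` over started tours.
#' @param seed Master seed; each (temperature, tour) gets a derived stream.
#' @param bias_depth Depth `h` of the pyramidal look-ahead bias (0 = off).
#'   The bias steers growth toward locally emptier regions and is exactly
#'   corrected in the weights, leaving all estimates unbiased.
#' @param population_control Apply prune/enrich (`TRUE`) or plain Rosenbluth
#'   growth (`FALSE`, for validation only).
#' @param lengths Chain lengths at which to report observables; default `N`.
#' @param L Box size when `lattice` is `NULL`; defaults to `2 * N + 3`,
#'   capped at 599 (the hard-box size used for production chains: reaching
#'   the wall would take some 300 net steps in one direction, so boundary
#'   effects are negligible while memory stays modest).
#' @param keep_tour_weights Keep per-tour `ln W` samples at length `N`
#'   (needed for [tour_weight_diagnostic()]).
#' @return A tibble of class `melt_curve` with one row per
#'   `(temp, n)`: columns `temp`, `beta`, `n`, `log_Z`, `mean_nc`, `var_nc`
#'   (the contact fluctuation `C_c`), `frac_bound = mean_nc / (n + 1)`,
#'   `n_samples`, and, for rows at `n == N`, list-columns `contact_dist`
#'   (tibble `n_c`, `prob`), `bubble_dist` (tibble `size`, `prob`),
#'   plus `mean_nb`, `tours`, `tours_reached` and (optionally) `ln_W`.
#' @examples
#' mc <- melt_curve(N = 20, temps = c(0.6, 0.8), tours = 200, seed = 1)
#' mc[, c("temp", "n", "mean_nc", "var_nc")]
#' @export
melt_curve <- function(lattice = NULL, N, temps, tours = 10000L, seed = 1L,
                       bias_depth = 0L, population_control = TRUE,
                       lengths = N, L = NULL, keep_tour_weights = FALSE) {
  if (is.null(lattice)) {
    if (is.null(L)) L <- min(2L * as.integer(N) + 3L, 599L)
    if (L %% 2L == 0L) L <- L + 1L
    lattice <- full_lattice(L)
  }
  stopifnot(inherits(lattice, "leath_lattice"))
  if (any(lengths > N)) abort("`lengths` cannot exceed `N`")
  if (any(temps <= 0)) abort("temperatures must be positive")

  rows <- purrr::imap(as.numeric(temps), function(temp, it) {
    res <- perm_run_cpp(lattice$state, lattice$L, as.integer(N), 1 / temp,
                        as.integer(tours),
                        as.numeric(derive_seed(seed, it)),
                        as.integer(bias_depth), population_control,
                        keep_tour_weights)
    at <- match(as.integer(lengths), res$n)
    out <- tibble(
      temp = temp, beta = 1 / temp, n = res$n[at],
      log_Z = res$log_Z[at],
      mean_nc = res$mean_nc[at],
      var_nc = pmax(res$mean_nc2[at] - res$mean_nc[at]^2, 0),
      frac_bound = res$mean_nc[at] / (res$n[at] + 1),
      log_sum_W = res$log_sum_W[at],
      n_samples = res$n_samples[at],
      tours = res$tours,
      tours_reached = res$tours_reached
    )
    isN <- out$n == N
    out$contact_dist <- replicate(nrow(out), NULL, simplify = FALSE)
    out$bubble_dist <- replicate(nrow(out), NULL, simplify = FALSE)
    out$mean_nb <- NA_real_
    if (any(isN)) {
      out$contact_dist[isN] <- list(tibble(n_c = 0:(N + 1), prob = res$p_nc))
      out$bubble_dist[isN] <- list(tibble(size = 0:N, prob = res$p_bubble))
      out$mean_nb[isN] <- res$mean_nb
    }
    if (keep_tour_weights) {
      out$ln_W <- replicate(nrow(out), NULL, simplify = FALSE)
      if (any(isN)) out$ln_W[isN] <- list(res$tour_lnW)
    }
    out
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("melt_curve", class(out))
  attr(out, "conditions") <- list(
    p = lattice$p, L = lattice$L, N = as.integer(N),
    tours = as.integer(tours), seed = as.integer(seed),
    bias_depth = as.integer(bias_depth),
    population_control = population_control
  )
  out
}

#' Single-temperature PERM run returning full per-length detail
#'
#' Lower-level interface used by [melt_curve()]; returns the raw per-length
#' accumulator summaries for one temperature, including the full `Z_n`
#' profile, useful for validation against exhaustive enumeration.
#'
#' @inheritParams melt_curve
#' @param temp One temperature.
#' @return A list: `n`, `log_Z`, `mean_nc`, `mean_nc2`, `n_samples`,
#'   `p_nc`, `p_bubble`, `mean_nb`, `tours`, `tours_reached`,
#'   `branches_reached`, `tour_lnW`.
#' @export
perm_run <- function(lattice, N, temp, tours = 10000L, seed = 1L,
                     bias_depth = 0L, population_control = TRUE,
                     keep_tour_weights = FALSE) {
  stopifnot(inherits(lattice, "leath_lattice"))
  perm_run_cpp(lattice$state, lattice$L, as.integer(N), 1 / temp,
               as.integer(tours), as.numeric(seed), as.integer(bias_depth),
               population_control, keep_tour_weights)
}
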