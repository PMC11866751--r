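#' Run a disorder ensemble: many lattice realizations, one PERM scan each
#'
#' For each realization a fresh spanning Leath lattice is grown (or the full
#' lattice when `p = 1`, where a single realization suffices) and a PERM
#' temperature scan is run on it.  The per-realization weighted sums are
#' returned so both disorder-averaging modes can be formed afterwards.
#'
#' @inheritParams melt_curve
#' @param p Retention probability of the medium.
#' @param L Box size (odd); the disordered medium is grown inside it.
#' @param realizations Number of independent disorder realizations.
#' @param method Leath growth order.
#' @param max_attempts Retry budget per spanning realization.
#' @return A tibble of class `disorder_ensemble` with one row per
#'   `(realization, temp, n)`: `realization`, `lattice_seed`, `attempts`,
#'   `temp`, `n`, `log_Z`, `mean_nc`, `mean_nc2`, `var_nc`, `mean_nb`,
#'   `tours`, `n_samples`, plus list-columns `contact_dist` and
#'   `bubble_dist` at the target length.  Failed realizations (no spanning
#'   cluster within the retry budget) are dropped with a warning and counted
#'   in the `n_failed` attribute.
#' @export
run_disorder_ensemble <- function(p, L, N, temps, realizations = 5L,
                                  tours = 10000L, seed = 1L, bias_depth = 0L,
                                  lengths = N,
                                  method = c("depth_first", "breadth_first"),
                                  max_attempts = 1000L) {
  method <- match.arg(method)
  rows <- list()
  n_failed <- 0L
  for (r in seq_len(realizations)) {
    lat_seed <- derive_seed(seed, 7919L * r)
    lat <- if (p >= 1) full_lattice(L) else
      tryCatch(spanning_lattice(L, p, seed = lat_seed,
                                max_attempts = max_attempts, method = method),
               crowdmelt_spanning_failure = function(e) NULL)
    if (is.null(lat)) { n_failed <- n_failed + 1L; next }
    mc <- melt_curve(lat, N = N, temps = temps, tours = tours,
                     seed = derive_seed(seed, 104729L * r),
                     bias_depth = bias_depth, lengths = lengths)
    mc$mean_nc2 <- mc$var_nc + mc$mean_nc^2
    mc$realization <- r
    mc$lattice_seed <- lat_seed
    mc$attempts <- if (is.null(lat$attempts)) 1L else lat$attempts
    rows[[length(rows) + 1L]] <- as_tibble(mc)
  }
  if (n_failed > 0)
    warn(sprintf("%d of %d realizations failed to span and were excluded",
                 n_failed, realizations))
  if (length(rows) == 0) abort("all realizations failed")
  out <- dplyr::bind_rows(rows)
  class(out) <- c("disorder_ensemble", class(out))
  attr(out, "conditions") <- list(p = p, L = L, N = as.integer(N),
                                  tours = as.integer(tours),
                                  realizations = as.integer(realizations),
                                  bias_depth = as.integer(bias_depth),
                                  seed = as.integer(seed), method = method)
  attr(out, "n_failed") <- n_failed
  out
}

#' Annealed disorder average
#'
#' Averages at the level of the partition sum: realizations are pooled with
#' weight `Z_n`, i.e. `[<Q>] = sum_r Z_r <Q>_r / sum_r Z_r`, and the
#' annealed free energy is `f_a = -T ln [Z_n]`.  This is the average the
#' chain-growth bookkeeping makes natural.
#'
#' @param ensemble A tibble from [run_disorder_ensemble()] (or any tibble
#'   with columns `temp`, `n`, `log_Z`, `mean_nc`, `mean_nc2`).
#' @return A tibble per `(temp, n)`: `mean_nc`, `var_nc`, `free_energy`,
#'   `n_real` (realizations with nonzero weight), `mode = "annealed"`.
#' @export
annealed_average <- function(ensemble) {
  dplyr::group_modify(
    dplyr::group_by(as_tibble(ensemble), .data$temp, .data$n),
    function(d, key) {
      ok <- is.finite(d$log_Z)
      if (!any(ok)) abort("all realizations have zero weight at some (T, n)")
      d <- d[ok, ]
      off <- max(d$log_Z)
      z <- exp(d$log_Z - off)          # relative Z_r, overflow-safe
      m1 <- sum(z * d$mean_nc) / sum(z)
      m2 <- sum(z * d$mean_nc2) / sum(z)
      tibble(mean_nc = m1, var_nc = max(m2 - m1^2, 0),
             free_energy = -key$temp * (off + log(mean(z))),
             n_real = nrow(d), mode = "annealed")
    }
  ) |> dplyr::ungroup()
}

#' Quenched disorder average
#'
#' Averages at the level of the free energy: each realization that produced
#' at least one chain of length `n` contributes its own thermal average with
#' equal weight, `[<Q>] = (1/C) sum_r <Q>_r`, and the quenched free energy is
#' `f_q = -T [ln Z_n]`.  Realizations with zero weight at `(T, n)` are
#' excluded and counted.
#'
#' @inheritParams annealed_average
#' @return A tibble per `(temp, n)`: `mean_nc`, `var_nc`, `free_energy`,
#'   `n_real`, `n_excluded`, `mode = "quenched"`.
#' @export
quenched_average <- function(ensemble) {
  dplyr::group_modify(
    dplyr::group_by(as_tibble(ensemble), .data$temp, .data$n),
    function(d, key) {
      ok <- is.finite(d$log_Z)
      if (!any(ok)) abort("no realization reached this length")
      kept <- d[ok, ]
      tibble(mean_nc = mean(kept$mean_nc),
             var_nc = max(mean(kept$mean_nc2) - mean(kept$mean_nc)^2, 0),
             free_energy = -key$temp * mean(kept$log_Z),
             n_real = nrow(kept), n_excluded = sum(!ok), mode = "quenched")
    }
  ) |> dplyr::ungroup()
}

#' Both disorder averages side by side
#'
#' @inheritParams annealed_average
#' @return Row-bound [annealed_average()] and [quenched_average()] results,
#'   distinguished by the `mode` column.
#' @export
disorder_average <- function(ensemble) {
  dplyr::bind_rows(annealed_average(ensemble), quenched_average(ensemble))
}
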