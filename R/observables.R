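#' Decompose a contact mask into bubbles and the Y-fork
#'
#' A bubble is a maximal run of broken base pairs enclosed between two bound
#' base pairs; its size is the index difference of the enclosing bound
#' indices, so the smallest bubble has size 2 (one broken index).  The open
#' run at the free end (the Y-fork) is not a bubble.  Index 0 is the pinned
#' origin and must be bound.
#'
#' @param contact_mask Logical (or 0/1) vector over monomer indices
#'   `0..n`; `TRUE` where the two strands are base-paired.
#' @return A list with `sizes` (integer vector of bubble sizes, possibly
#'   empty), `n_b` (bubble count), and `fork_length` (number of trailing
#'   unbound indices).
#' @examples
#' bubble_decompose(c(1, 0, 1))          # one minimal bubble, size 2
#' bubble_decompose(c(1, 0, 0, 1, 0, 0)) # one bubble of size 3, fork of 2
#' @export
bubble_decompose <- function(contact_mask) {
  m <- as.logical(contact_mask)
  if (length(m) == 0 || !m[1])
    abort("index 0 (the pinned origin) must be bound")
  bound_idx <- which(m) - 1L  # 0-based
  gaps <- diff(bound_idx)
  sizes <- gaps[gaps >= 2L]
  list(sizes = as.integer(sizes), n_b = length(sizes),
       fork_length = length(m) - 1L - bound_idx[length(bound_idx)])
}

#' Weighted thermal average
#'
#' The expectation of an observable under chain-growth sampling is the ratio
#' of weighted sums, `<Q> = sum(W * Q) / sum(W)`.
#'
#' @param w Nonnegative sample weights.
#' @param q Observable values, same length as `w`.
#' @return The weighted mean; errors if all weights are zero.
#' @export
thermal_average <- function(w, q) {
  if (length(w) != length(q)) abort("`w` and `q` must have equal length")
  if (any(w < 0)) abort("weights must be nonnegative")
  sw <- sum(w)
  if (sw <= 0) abort("total weight is zero; thermal average undefined")
  sum(w * q) / sw
}

#' Contact fluctuation from weighted samples
#'
#' The thermal response `C_c = <n_c^2> - <n_c>^2`, the configuration
#' variance of the number of bound base pairs.  Near the melting point it
#' collapses as `C_c / N^(2 phi)` against `(T - T_m) N^phi`.
#'
#' @inheritParams thermal_average
#' @param nc Contact numbers per sample.
#' @return The weighted variance (clamped at 0 against rounding).
#' @export
contact_fluctuation <- function(w, nc) {
  m1 <- thermal_average(w, nc)
  m2 <- thermal_average(w, nc^2)
  v <- m2 - m1^2
  if (v < -1e-8 * max(m2, 1)) abort("negative variance beyond rounding")
  max(v, 0)
}

#' Extract the order-parameter distribution from a melt curve
#'
#' @param curve A `melt_curve` tibble.
#' @param temp Temperature of the row to extract (nearest match).
#' @return A tibble `n_c`, `prob` (sums to 1) at the target length.
#' @export
contact_distribution <- function(curve, temp) {
  row <- nearest_N_row(curve, temp)
  row$contact_dist[[1]]
}

#' Extract bubble statistics from a melt curve
#'
#' @inheritParams contact_distribution
#' @return A list with `dist` (tibble `size`, `prob`, normalized over
#'   observed bubbles) and `mean_nb` (weighted mean bubble count per
#'   configuration).
#' @export
bubble_statistics <- function(curve, temp) {
  row <- nearest_N_row(curve, temp)
  d <- row$bubble_dist[[1]]
  if (is.null(d) || sum(d$prob) == 0)
    warn("no bubbles observed at this temperature")
  list(dist = d, mean_nb = row$mean_nb)
}

nearest_N_row <- function(curve, temp) {
  stopifnot(inherits(curve, "melt_curve"))
  N <- attr(curve, "conditions")$N
  rows <- dplyr::filter(curve, .data$n == N)
  if (nrow(rows) == 0) abort("melt curve has no rows at the target length")
  rows[which.min(abs(rows$temp - temp)), ]
}

#' Tour-weight sampling diagnostic
#'
#' Compares the distribution of tour log-weights `P(ln W)` with the
#' weight-rescaled distribution `W P(ln W)`.  Sampling is trustworthy when
#' the mass of `W P(ln W)` lies where `P(ln W)` is appreciable; if the
#' rescaled distribution peaks in the sparse upper tail, a few rare tours
#' dominate the estimate and it cannot be trusted.
#'
#' @param ln_w Per-tour log weights at the target length (e.g. the `ln_W`
#'   list-column of a [melt_curve()] run with `keep_tour_weights = TRUE`).
#' @param bins Number of histogram bins on the common `ln W` grid.
#' @param floor_frac `P(ln W)` is "appreciable" in bins holding at least
#'   this fraction of its maximum bin mass.
#' @return An object of class `tour_weight_diag`: a list with `hist`
#'   (tibble `ln_w`, `p`, `wp`, both normalized), `overlap` (fraction of
#'   `W P` mass in appreciable-`P` bins, near 1 for healthy sampling), and
#'   `n_tours`.  Fewer than 100 tours flags the diagnostic unreliable.
#' @export
tour_weight_diagnostic <- function(ln_w, bins = 40L, floor_frac = 0.01) {
  ln_w <- ln_w[is.finite(ln_w)]
  n <- length(ln_w)
  reliable <- n >= 100
  if (n == 0) abort("no finite tour weights supplied")
  rng <- range(ln_w)
  if (diff(rng) == 0) {
    h <- tibble(ln_w = rng[1], p = 1, wp = 1)
    out <- list(hist = h, overlap = 1, n_tours = n, reliable = reliable)
    class(out) <- "tour_weight_diag"
    return(out)
  }
  br <- seq(rng[1], rng[2], length.out = bins + 1)
  bin <- findInterval(ln_w, br, rightmost.closed = TRUE)
  p <- tabulate(bin, nbins = bins)
  # weights offset by max so W P(ln W) cannot overflow
  wscaled <- exp(ln_w - max(ln_w))
  wp <- vapply(seq_len(bins), function(b) sum(wscaled[bin == b]), 0)
  h <- tibble(ln_w = (br[-1] + br[-length(br)]) / 2,
              p = p / sum(p), wp = wp / sum(wp))
  appreciable <- h$p >= floor_frac * max(h$p)
  out <- list(hist = h, overlap = sum(h$wp[appreciable]), n_tours = n,
              reliable = reliable)
  class(out) <- "tour_weight_diag"
  out
}

#' @export
print.tour_weight_diag <- function(x, ...) {
  cat(sprintf("<tour_weight_diag> %d tours, overlap = %.3f%s\n", x$n_tours,
              x$overlap,
              if (!x$reliable) " (UNRELIABLE: < 100 tours)" else ""))
  invisible(x)
}
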