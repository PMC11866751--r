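#' Exhaustive enumeration of dual-strand configurations (ground truth)
#'
#' Depth-first enumeration of every legal ordered step-pair sequence for the
#' two strands up to length `n` -- self-avoiding, mutually avoiding except
#' for equal-index base pairing -- with exact Boltzmann sums.  The state
#' space mirrors the PERM sampler exactly, so `Z_n` definitions match
#' constant for constant; this is the independent oracle every estimator is
#' validated against.  Cost grows like `36^n`; lengths above 6 are refused.
#'
#' @param n Chain length (number of base-pair steps), `n <= 6`.
#' @param lattice A `leath_lattice`; `NULL` means a full lattice large
#'   enough that the box never interferes.
#' @param beta Inverse temperature (Boltzmann factor `exp(beta)` per
#'   contact).
#' @return An object of class `exact_summary`: a list with `n`, `beta`,
#'   `Z` (exact partition sums for lengths `0..n`), `mean_nc`, `var_nc`,
#'   `p_nc` (tibble `n_c`, `prob` at length `n`), `bubble` (tibble `size`,
#'   `prob`), `mean_nb`, and `n_configs` (number of legal length-`n`
#'   configurations; equals `Z_n` at `beta = 0`).
#' @examples
#' enumerate_dual_walks(1, beta = 0)$Z[2]   # 36 ordered neighbour pairs
#' @export
enumerate_dual_walks <- function(n, lattice = NULL, beta = 0) {
  n <- as.integer(n)
  if (n < 1) abort("`n` must be >= 1")
  if (is.null(lattice)) lattice <- full_lattice(2L * n + 3L)
  stopifnot(inherits(lattice, "leath_lattice"))
  res <- enumerate_dual_cpp(lattice$state, lattice$L, n, beta)
  ZN <- res$Z[n + 1]
  mean_nc <- res$Znc / ifelse(res$Z > 0, res$Z, NA)
  var_nc <- res$Znc2 / ifelse(res$Z > 0, res$Z, NA) - mean_nc^2
  btot <- sum(res$bubbleZ)
  out <- list(
    n = n, beta = beta,
    Z = res$Z, mean_nc = mean_nc, var_nc = pmax(var_nc, 0),
    p_nc = tibble(n_c = 0:(n + 1),
                  prob = if (ZN > 0) res$constrained / ZN else NA_real_),
    bubble = tibble(size = 0:n,
                    prob = if (btot > 0) res$bubbleZ / btot else 0),
    mean_nb = if (ZN > 0) res$Znb / ZN else NA_real_,
    n_configs = res$n_configs
  )
  class(out) <- "exact_summary"
  out
}

#' @export
print.exact_summary <- function(x, ...) {
  cat(sprintf("<exact_summary> n = %d, beta = %.3f\n", x$n, x$beta))
  cat(sprintf("  Z_n = %.6g over %s configurations; <n_c> = %.4f\n",
              x$Z[x$n + 1], format(x$n_configs, big.mark = ","),
              x$mean_nc[x$n + 1]))
  invisible(x)
}
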