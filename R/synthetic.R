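#' Synthetic curve family that collapses exactly
#'
#' Generates order-parameter-like curves from the scaling form
#' `value = N^(mult * phi) * h((T - t_m) N^phi)` with a smooth sigmoidal
#' master curve `h(x) = (n_max/N^phi) / (1 + exp(x))` for `n_c`-like data,
#' or a Lorentzian bump for `C_c`-like data.  Used for generate-and-recover
#' tests of [fit_collapse()].
#'
#' @param t_m,phi True melting point and crossover exponent.
#' @param N Vector of chain lengths.
#' @param temps Temperature grid.
#' @param observable `"n_c"` (ordinate scales like `N^phi`) or `"C_c"`
#'   (`N^(2 phi)`).
#' @param noise_sd Relative Gaussian noise added to each point.
#' @param seed RNG seed for the noise.
#' @return A tibble `N`, `temp`, `value` suitable for [fit_collapse()].
#' @export
synthetic_collapse_curves <- function(t_m = 0.75, phi = 1,
                                      N = c(50, 100, 200),
                                      temps = seq(0.70, 0.80, by = 0.005),
                                      observable = c("n_c", "C_c"),
                                      noise_sd = 0, seed = 1L) {
  observable <- match.arg(observable)
  mult <- if (observable == "n_c") 1 else 2
  withr_seed(seed, {
    d <- tidyr::expand_grid(N = N, temp = temps)
    x <- (d$temp - t_m) * d$N^phi
    h <- if (observable == "n_c") 1 / (1 + exp(x)) else 1 / (1 + x^2)
    d$value <- d$N^(mult * phi) * h * (1 + stats::rnorm(nrow(d), 0, noise_sd))
    d
  })
}

#' Sample bubble sizes from an exact discrete power law
#'
#' Draws integer sizes with `P(l) proportional to l^(-c)` on
#' `[size_min, size_max]` by inverse-CDF sampling, and returns both the
#' samples and their normalized histogram.  Used for generate-and-recover
#' tests of [fit_bubble_exponent()].
#'
#' @param n Number of draws.
#' @param c_true Power-law exponent.
#' @param size_min,size_max Support.
#' @param seed RNG seed.
#' @return A list with `sizes` (integer draws) and `dist` (tibble `size`,
#'   `prob`).
#' @export
synthetic_powerlaw <- function(n = 1e5, c_true = 2.5, size_min = 2,
                               size_max = 500, seed = 1L) {
  sizes <- size_min:size_max
  w <- sizes^(-c_true)
  p <- w / sum(w)
  draws <- withr_seed(seed, sample(sizes, n, replace = TRUE, prob = p))
  tab <- table(factor(draws, levels = sizes))
  list(sizes = draws,
       dist = tibble(size = sizes, prob = as.numeric(tab) / n))
}

#' Tiny fixture lattices with prescribed dilution patterns
#'
#' Deterministic small lattices for unit tests: the dilution pattern (hence
#' every downstream quantity) is known by construction.
#'
#' @param kind One of `"open"` (full `L = 9` box), `"two_diluted"` (full box
#'   with 2 of the centre's 6 neighbours diluted, so the first enumeration
#'   step has `4 x 4 = 16` pairs), `"blocked"` (all 6 centre neighbours
#'   diluted: dead at step one), `"plane"` (only the central `z` plane
#'   available: an exactly two-dimensional cluster), or `"checker"` (sparse
#'   deterministic dilution away from the centre, a generic diluted
#'   fixture).
#' @param L Box size.
#' @return A `leath_lattice`.
#' @export
tiny_lattice <- function(kind = c("open", "two_diluted", "blocked", "plane",
                                  "checker"),
                         L = 9L) {
  kind <- match.arg(kind)
  lat <- full_lattice(L)
  c0 <- (L - 1L) / 2L
  at <- function(x, y, z) 1L + x + L * (y + L * z)  # 0-based coords
  if (kind == "two_diluted") {
    lat$state[at(c0 + 1L, c0, c0)] <- 0L
    lat$state[at(c0, c0 + 1L, c0)] <- 0L
  } else if (kind == "blocked") {
    for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1)))
      lat$state[at(c0 + d[1], c0 + d[2], c0 + d[3])] <- 0L
  } else if (kind == "plane") {
    st <- array(0L, dim = c(L, L, L))
    st[, , c0 + 1L] <- 1L
    lat$state <- as.integer(st)
    lat$cluster_size <- as.numeric(L)^2
  } else if (kind == "checker") {
    st <- array(lat$state, dim = c(L, L, L))
    for (x in 0:(L - 1)) for (y in 0:(L - 1)) for (z in 0:(L - 1)) {
      far <- max(abs(x - c0), abs(y - c0), abs(z - c0)) >= 2
      if (far && (x + 2 * y + 3 * z) %% 5 == 0) st[x + 1, y + 1, z + 1] <- 0L
    }
    lat$state <- as.integer(st)
    lat$cluster_size <- sum(lat$state == 1L)
  }
  lat$p <- NA_real_
  lat$method <- paste0("fixture_", kind)
  lat
}

#' Hand-built contact masks with known bubble decompositions
#'
#' @return A list of named cases, each a list with `mask`, and the expected
#'   `sizes`, `n_b`, `fork_length`.
#' @export
handmade_configs <- function() {
  list(
    zipped = list(mask = rep(1, 6), sizes = integer(0), n_b = 0,
                  fork_length = 0),
    minimal_bubble = list(mask = c(1, 0, 1), sizes = 2L, n_b = 1,
                          fork_length = 0),
    bubble_and_fork = list(mask = c(1, 0, 0, 1, 0, 0), sizes = 3L, n_b = 1,
                           fork_length = 2),
    two_bubbles = list(mask = c(1, 0, 1, 0, 0, 0, 1, 1), sizes = c(2L, 4L),
                       n_b = 2, fork_length = 0),
    origin_only = list(mask = c(1, 0, 0, 0), sizes = integer(0), n_b = 0,
                       fork_length = 3)
  )
}

#' Deterministic test-input factory
#'
#' One entry point over the fixture builders, keyed by kind.
#'
#' @param kind `"tiny_lattices"`, `"handmade_configs"`,
#'   `"synthetic_powerlaw"` or `"synthetic_collapse"`.
#' @param seed Seed passed to the stochastic generators.
#' @return The corresponding fixture object.
#' @export
fixture_generator <- function(kind, seed = 1L) {
  switch(kind,
    tiny_lattices = lapply(
      c("open", "two_diluted", "blocked", "plane", "checker"),
      tiny_lattice),
    handmade_configs = handmade_configs(),
    synthetic_powerlaw = synthetic_powerlaw(seed = seed),
    synthetic_collapse = synthetic_collapse_curves(seed = seed),
    abort(sprintf("unknown fixture kind '%s'", kind))
  )
}

# evaluate expr under a local RNG seed without touching the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
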