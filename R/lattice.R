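#' Grow a site-percolation cluster with the Leath algorithm
#'
#' Starting from the occupied centre of an `L^3` box, neighbouring sites are
#' visited and retained with probability `p` (diluted otherwise); retained
#' sites are pushed onto the growth front and their neighbours visited in
#' turn.  Each site's dilution status is decided exactly once at first visit,
#' so the disorder is quenched.  Growth halts at the box faces.  Diluted
#' sites model inert macromolecular crowders: the DNA strands may never
#' occupy them.
#'
#' @param L Odd linear dimension of the cubic box (sites per edge), `L >= 3`.
#' @param p Site retention probability in `[0, 1]`; the crowder density is
#'   `1 - p`.
#' @param seed Integer seed for the lattice's private random stream.
#' @param method `"depth_first"` (LIFO growth front) or `"breadth_first"`
#'   (FIFO).  Cluster shapes differ but their statistics do not.
#' @return An object of class `leath_lattice`: a list with `state` (integer
#'   vector of length `L^3`; 0 = diluted, 1 = available, 2 = occupied by a
#'   chain), `visited`, `L`, `p`, `seed`, `method`, `cluster_size`, and
#'   `seed_site` (0-based `(x, y, z)` of the centre).
#' @examples
#' lat <- leath_lattice(L = 9, p = 0.6, seed = 1)
#' lat
#' is_spanning(lat)
#' @export
leath_lattice <- function(L, p, seed = 1L,
                          method = c("depth_first", "breadth_first")) {
  method <- match.arg(method)
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
    abort("`p` must be a single probability in [0, 1].")
  if (!is.numeric(L) || length(L) != 1 || L < 3 || L %% 2 != 1)
    abort("`L` must be an odd integer >= 3 (a unique centre must exist).")
  res <- leath_grow_cpp(as.integer(L), p, as.numeric(seed),
                        method == "breadth_first")
  structure(
    list(state = res$state, visited = res$visited, L = as.integer(L), p = p,
         seed = as.integer(seed), method = method,
         cluster_size = res$cluster_size,
         seed_site = rep((L - 1L) / 2L, 3L)),
    class = "leath_lattice"
  )
}

#' Full (undiluted) lattice
#'
#' Convenience constructor for the `p = 1` case: every site available.
#'
#' @inheritParams leath_lattice
#' @return A `leath_lattice` with all sites available.
#' @export
full_lattice <- function(L) {
  if (!is.numeric(L) || length(L) != 1 || L < 3 || L %% 2 != 1)
    abort("`L` must be an odd integer >= 3.")
  L <- as.integer(L)
  structure(
    list(state = rep(1L, L^3), visited = NULL, L = L, p = 1,
         seed = NA_integer_, method = "full", cluster_size = as.numeric(L)^3,
         seed_site = rep((L - 1L) / 2L, 3L)),
    class = "leath_lattice"
  )
}

#' @export
print.leath_lattice <- function(x, ...) {
  cat(sprintf("<leath_lattice> L = %d, p = %.4f, method = %s\n",
              x$L, x$p, x$method))
  cat(sprintf("  cluster: %s of %s sites (%.1f%% of box), spanning: %s\n",
              format(x$cluster_size, big.mark = ","),
              format(as.numeric(x$L)^3, big.mark = ","),
              100 * x$cluster_size / as.numeric(x$L)^3,
              is_spanning(x)))
  invisible(x)
}

#' Does the grown cluster span the box?
#'
#' A cluster spans when it has at least one site on each of the six faces of
#' the cube.  Leath growth guarantees connectedness, so face presence on all
#' six faces certifies an "infinite" (box-spanning) cluster.
#'
#' @param lattice A `leath_lattice`.
#' @return `TRUE` or `FALSE`.
#' @export
is_spanning <- function(lattice) {
  stopifnot(inherits(lattice, "leath_lattice"))
  is_spanning_cpp(lattice$state, lattice$L)
}

#' Generate a spanning cluster, retrying non-spanning realizations
#'
#' Repeats Leath growth with fresh sub-seeds until the cluster touches all
#' six faces, mirroring the discard-and-retry procedure used to obtain the
#' infinite cluster at and above the percolation threshold.
#'
#' @inheritParams leath_lattice
#' @param max_attempts Give up (with an error carrying the attempt count)
#'   after this many non-spanning realizations.
#' @return A spanning `leath_lattice` with an `attempts` field.
#' @export
spanning_lattice <- function(L, p, seed = 1L, max_attempts = 1000L,
                             method = c("depth_first", "breadth_first")) {
  method <- match.arg(method)
  if (max_attempts < 1) abort("`max_attempts` must be >= 1.")
  for (a in seq_len(max_attempts)) {
    # distinct deterministic sub-seed per attempt
    lat <- leath_lattice(L, p, seed = derive_seed(seed, a), method = method)
    if (is_spanning(lat)) {
      lat$attempts <- a
      return(lat)
    }
  }
  abort(
    sprintf("no spanning cluster in %d attempts (p = %.4f likely too small or L = %d too large)",
            max_attempts, p, L),
    class = "crowdmelt_spanning_failure",
    attempts = max_attempts
  )
}

# deterministic 32-bit sub-seed derivation (keeps seeds in integer range)
derive_seed <- function(seed, k) {
  x <- (as.numeric(seed) * 2654435761 + k * 40503) %% 2147483647
  as.integer(x) + 1L
}

#' Spanning probability curves over a grid of (p, L)
#'
#' For each retention probability and box size, grows `realizations`
#' independent Leath clusters and records the fraction that span all six
#' faces.  The curves for different `L` cross close to the site-percolation
#' threshold of the cubic lattice, `p_c = 0.3116`.
#'
#' @param p Numeric vector of retention probabilities.
#' @param L Integer vector of odd box sizes.
#' @param realizations Clusters grown per `(p, L)` point.
#' @param seed Master seed; every realization gets a derived sub-seed.
#' @param method Growth order, as in [leath_lattice()].
#' @return A tibble with columns `p`, `L`, `realizations`, `spanning_frac`,
#'   and the binomial standard error `se`.
#' @export
spanning_curve <- function(p, L, realizations = 2000L, seed = 1L,
                           method = c("depth_first", "breadth_first")) {
  method <- match.arg(method)
  grid <- tidyr::expand_grid(p = p, L = as.integer(L))
  grid$cell <- seq_len(nrow(grid))
  res <- purrr::pmap(grid, function(p, L, cell) {
    hits <- 0L
    for (r in seq_len(realizations)) {
      lat <- leath_lattice(L, p, seed = derive_seed(seed, cell * 10000019 + r),
                           method = method)
      if (is_spanning(lat)) hits <- hits + 1L
    }
    frac <- hits / realizations
    tibble(p = p, L = L, realizations = as.integer(realizations),
           spanning_frac = frac,
           se = sqrt(pmax(frac * (1 - frac), 1 / realizations) / realizations))
  })
  dplyr::bind_rows(res)
}

#' Estimate the percolation threshold from curve crossings
#'
#' The spanning probability rises from 0 to 1 more steeply the larger the
#' box, so curves for two sizes cross near the threshold.  For every pair of
#' sizes, the crossing of the linearly interpolated difference is located;
#' the estimate is the mean over pairs.
#'
#' @param curves A tibble from [spanning_curve()] with at least two `L`.
#' @return A list with `p_c` (the estimate), and `crossings`, a tibble of
#'   per-pair crossing points.
#' @export
estimate_threshold <- function(curves) {
  Ls <- sort(unique(curves$L))
  if (length(Ls) < 2) abort("need spanning curves for at least two L values")
  pairs <- utils::combn(Ls, 2, simplify = FALSE)
  cross <- purrr::map_dfr(pairs, function(pr) {
    a <- dplyr::arrange(dplyr::filter(curves, .data$L == pr[1]), .data$p)
    b <- dplyr::arrange(dplyr::filter(curves, .data$L == pr[2]), .data$p)
    p_grid <- intersect(a$p, b$p)
    a <- a[match(p_grid, a$p), ]
    b <- b[match(p_grid, b$p), ]
    d <- b$spanning_frac - a$spanning_frac
    i <- which(d[-length(d)] * d[-1] <= 0 & abs(diff(d)) > 0)
    if (length(i) == 0) return(tibble(L1 = pr[1], L2 = pr[2], p_cross = NA_real_))
    # closest-to-median crossing guards against noise-induced extra roots
    i <- i[which.min(abs(i - length(d) / 2))]
    p_cross <- p_grid[i] - d[i] * (p_grid[i + 1] - p_grid[i]) / (d[i + 1] - d[i])
    tibble(L1 = pr[1], L2 = pr[2], p_cross = p_cross)
  })
  list(p_c = mean(cross$p_cross, na.rm = TRUE), crossings = cross)
}

#' Mass-radius profile of a cluster
#'
#' Cumulative number of cluster sites within concentric Euclidean shells of
#' unit width about the cluster's centre of mass.  For a fractal cluster the
#' mass grows as `M ~ r^d_f`.
#'
#' @param lattice A `leath_lattice` (a spanning cluster for fractal analysis).
#' @param r_max Largest shell radius; defaults to `L / 2`.
#' @return A tibble with columns `radius` and `mass` (nondecreasing).
#' @export
mass_radius <- function(lattice, r_max = NULL) {
  stopifnot(inherits(lattice, "leath_lattice"))
  if (is.null(r_max)) r_max <- floor(lattice$L / 2)
  prof <- mass_radius_cpp(lattice$state, lattice$L, as.integer(r_max))
  tibble(radius = prof$radius, mass = prof$mass)
}

#' Mass fractal dimension from the mass-radius scaling
#'
#' Least-squares slope of `log(mass)` against `log(radius)` over
#' `[r_min, r_max]`.  At the percolation threshold the spanning cluster has
#' `d_f = 2.52` in three dimensions; the full lattice gives `d_f = 3`.
#' The fit window is exposed because intermediate radii (above the lattice
#' constant, below the box edge) are where the power law holds.
#'
#' @param lattice A `leath_lattice`, or a [mass_radius()] profile tibble.
#' @param r_min,r_max Fit window in lattice units.
#' @return A list with `d_f`, `se`, and the `profile` points used.
#' @export
fractal_dimension <- function(lattice, r_min = 2, r_max = NULL) {
  if (inherits(lattice, "leath_lattice")) {
    if (is.null(r_max)) r_max <- floor(lattice$L / 4)
    prof <- mass_radius(lattice, r_max = floor(lattice$L / 2))
  } else {
    prof <- lattice
    if (is.null(r_max)) r_max <- max(prof$radius)
  }
  use <- prof$radius >= r_min & prof$radius <= r_max & prof$mass > 0
  if (sum(use) < 3) abort("fewer than 3 radii in the fit window")
  fit <- lm(log(mass) ~ log(radius), data = prof[use, ])
  list(d_f = unname(coef(fit)[2]),
       se = unname(sqrt(diag(vcov(fit)))[2]),
       profile = prof[use, ])
}

#' Ensemble-averaged mass fractal dimension of spanning clusters
#'
#' Grows spanning clusters at retention probability `p`, averages their
#' mass-radius profiles, and fits the mass-radius slope once on the averaged
#' profile.  Averaging before fitting is essential: a single cluster's
#' centre of mass often sits in a sparse region (depleting small radii), and
#' the box saturates large radii, leaving only an intermediate scaling
#' window.  The default window `[L/8, L/2]` excludes the centre-of-mass
#' depletion scale while spanning the regime the box still resolves.
#'
#' @inheritParams spanning_lattice
#' @param clusters Number of spanning clusters to average over.
#' @param window Fit window in lattice units; default `c(L/8, L/2)`.
#' @return A list with `d_f`, `se` (from the least-squares fit on the
#'   averaged profile), `profile` (the averaged mass-radius tibble), and
#'   `clusters`.
#' @export
fractal_dimension_ensemble <- function(p, L, clusters = 50L, seed = 1L,
                                       window = NULL, max_attempts = 5000L) {
  if (is.null(window)) window <- c(L / 8, L / 2)
  profs <- purrr::map(seq_len(clusters), function(i) {
    lat <- spanning_lattice(L, p, seed = derive_seed(seed, i),
                            max_attempts = max_attempts)
    mass_radius(lat)
  })
  avg <- dplyr::bind_rows(profs) |>
    dplyr::group_by(.data$radius) |>
    dplyr::summarise(mass = mean(.data$mass), .groups = "drop")
  fit <- fractal_dimension(avg, r_min = window[1], r_max = window[2])
  list(d_f = fit$d_f, se = fit$se, profile = avg, clusters = clusters)
}
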