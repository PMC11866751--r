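#' Write a lattice to a run-length-encoded text file
#'
#' Plain-text, human-inspectable serialization: a header with the generation
#' parameters followed by run-length pairs `<code> <count>` over sites in
#' x-fastest order.  Occupancy code 2 (chain monomers) is transient sampler
#' state and is written as-is; normally lattices are serialized between
#' generation and use, when only codes 0 and 1 occur.
#'
#' @param lattice A `leath_lattice`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lattice <- function(lattice, path) {
  stopifnot(inherits(lattice, "leath_lattice"))
  s <- lattice$state
  r <- rle(s)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# crowdmelt lattice v1",
    sprintf("L %d", lattice$L),
    sprintf("p %.17g", lattice$p),
    sprintf("seed %d", if (is.na(lattice$seed)) -1L else lattice$seed),
    sprintf("method %s", lattice$method),
    sprintf("runs %d", length(r$lengths))
  ), con)
  writeLines(sprintf("%d %d", r$values, r$lengths), con)
  invisible(path)
}

#' Read a lattice written by [write_lattice()]
#'
#' Validates the structural invariants on load: site codes restricted to
#' {0, 1, 2}, total site count `L^3`, and an available (non-diluted) seed
#' site at the centre.
#'
#' @param path File written by [write_lattice()].
#' @return A `leath_lattice`.  The `visited` field is not serialized (it is
#'   only meaningful during generation) and is restored as `NULL`.
#' @export
read_lattice <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7 || lines[1] != "# crowdmelt lattice v1")
    abort("not a crowdmelt lattice file")
  hdr <- strsplit(lines[2:6], " ", fixed = TRUE)
  field <- function(i, name) {
    if (hdr[[i]][1] != name) abort(sprintf("malformed header: expected '%s'", name))
    hdr[[i]][2]
  }
  L <- as.integer(field(1, "L"))
  p <- as.numeric(field(2, "p"))
  seed <- as.integer(field(3, "seed"))
  method <- field(4, "method")
  n_runs <- as.integer(field(5, "runs"))
  body <- do.call(rbind, strsplit(lines[7:(6 + n_runs)], " ", fixed = TRUE))
  vals <- as.integer(body[, 1])
  lens <- as.integer(body[, 2])
  if (!all(vals %in% 0:2)) abort("invalid site codes (must be 0, 1 or 2)")
  state <- inverse.rle(structure(list(lengths = lens, values = vals),
                                 class = "rle"))
  if (length(state) != as.numeric(L)^3)
    abort(sprintf("site count %d does not match L^3 = %d", length(state), L^3))
  c0 <- (L - 1L) / 2L
  if (state[1 + c0 + L * (c0 + L * c0)] == 0)
    abort("seed site is diluted; invalid lattice")
  structure(
    list(state = state, visited = NULL, L = L, p = p,
         seed = if (seed < 0) NA_integer_ else seed, method = method,
         cluster_size = sum(state >= 1), seed_site = rep(c0, 3L)),
    class = "leath_lattice"
  )
}
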