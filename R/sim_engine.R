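#' Simulation parameters for 3D barcoded tumor growth
#'
#' Bundles the cellular rate constants and lattice geometry for the
#' agent-based growth model. Each cell on the lattice carries three event
#' rates: a birth rate (division into an adjacent empty site, the daughter
#' inheriting the parent's barcode), a death rate, and a mobility rate
#' (short-range hop to an adjacent empty site). Rates are per cell per unit
#' time in arbitrary units; only their ratios matter for the clonal pattern.
#'
#' The default rates are configuration placeholders in the spirit of
#' lattice models of spatial tumor growth; they are not calibrated to any
#' particular tumor and should be overridden when a calibration is
#' available.
#'
#' @param birth_rate Division rate per cell (must be >= 0; growth requires
#'   a positive value).
#' @param death_rate Death rate per cell (>= 0).
#' @param mobility Short-range migration rate per cell (>= 0).
#' @param target_size Number of cells at which growth stops.
#' @param lattice_extent Number of lattice sites per axis. `NULL` (default)
#'   chooses an extent that comfortably contains a ball of `target_size`
#'   cells.
#' @param neighborhood 26 (Moore, default) or 6 (von Neumann) connectivity.
#' @param rng_seed Integer seed making trajectories reproducible, or `NULL`
#'   to continue the session RNG stream.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(birth_rate = 0.69, death_rate = 0.1, mobility = 0.05,
                       target_size = 2e5, lattice_extent = NULL,
                       neighborhood = 26, rng_seed = NULL) {
  stopifnot(is.numeric(birth_rate), length(birth_rate) == 1, birth_rate >= 0,
            is.numeric(death_rate), length(death_rate) == 1, death_rate >= 0,
            is.numeric(mobility), length(mobility) == 1, mobility >= 0,
            is.numeric(target_size), length(target_size) == 1, target_size >= 1)
  if (!neighborhood %in% c(6L, 26L))
    stop("`neighborhood` must be 6 or 26")
  if (is.null(lattice_extent)) {
    # ball radius for target_size cells, with a wide margin for surface
    # roughness so the growing front never touches the boundary
    r <- (3 * target_size / (4 * pi))^(1 / 3)
    lattice_extent <- as.integer(ceiling(2.6 * r) + 6)
  }
  lattice_extent <- as.integer(lattice_extent)
  if (lattice_extent^3 <= target_size)
    stop("lattice capacity (", lattice_extent, "^3) does not exceed ",
         "target_size (", target_size, ")")
  structure(list(birth_rate = birth_rate, death_rate = death_rate,
                 mobility = mobility, target_size = as.integer(target_size),
                 lattice_extent = lattice_extent,
                 neighborhood = as.integer(neighborhood),
                 rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)),
            class = "sim_params")
}

#' Seed a tumor with barcoded founder cells
#'
#' Places `n_founders` cells in a densest-packed ball centered on the
#' lattice midpoint. Each founder receives a distinct heritable barcode ID
#' (1..n_founders), assigned in placement order (sites sorted by squared
#' distance to the center, ties broken lexicographically), so seeding is
#' fully deterministic.
#'
#' @param n_founders Number of barcoded tumor-initiating cells (>= 1).
#' @param params A [sim_params()] object.
#' @return A `tumor_state` object.
#' @export
initialize_tumor <- function(n_founders, params = sim_params()) {
  if (!is.numeric(n_founders) || length(n_founders) != 1 ||
      n_founders < 1 || n_founders != round(n_founders))
    stop("`n_founders` must be a positive integer")
  n_founders <- as.integer(n_founders)
  stopifnot(inherits(params, "sim_params"))
  if (n_founders > params$target_size)
    stop("n_founders exceeds target_size")
  L <- params$lattice_extent
  if (L^3 < n_founders)
    stop("lattice too small to seed ", n_founders, " founder cells")
  mid <- (L - 1) / 2
  # enumerate candidate sites in a cube around the center just large enough
  r0 <- ceiling((3 * n_founders / (4 * pi))^(1 / 3)) + 2
  rng <- max(0, floor(mid - r0)):min(L - 1, ceiling(mid + r0))
  if (length(rng)^3 < n_founders) rng <- 0:(L - 1)
  g <- expand.grid(x = rng, y = rng, z = rng)
  d2 <- (g$x - mid)^2 + (g$y - mid)^2 + (g$z - mid)^2
  ord <- order(d2, g$x, g$y, g$z)[seq_len(n_founders)]
  coords <- as.matrix(g[ord, c("x", "y", "z")])
  dimnames(coords) <- NULL
  storage.mode(coords) <- "integer"
  structure(list(coords = coords,
                 barcode = seq_len(n_founders),
                 extent = L,
                 params = params,
                 n_events = 0,
                 status = "initialized"),
            class = "tumor_state")
}

#' Grow a tumor to its target size
#'
#' Runs the kinetic Monte Carlo loop: at each event a cell is chosen
#' uniformly (all cells share the same total rate b+d+M), then the event
#' type is chosen with probabilities proportional to b:d:M. Birth places a
#' daughter carrying the parent's barcode in a uniformly chosen empty
#' neighbor site (no empty neighbor: the division attempt is suppressed);
#' death frees the site for reuse; mobility hops the cell to a uniformly
#' chosen empty neighbor site. The loop stops when the population reaches
#' `target_size` or goes extinct. Identical `(params, rng_seed)` reproduce
#' identical trajectories.
#'
#' @param state A `tumor_state` from [initialize_tumor()].
#' @param params A [sim_params()]; defaults to the one stored in `state`.
#' @param max_events Safety cap on the number of simulated events.
#' @return An updated `tumor_state` whose `status` is `"reached"` or
#'   `"extinct"` (extinction is an explicit result, not an error).
#' @export
grow_to <- function(state, params = state$params,
                    max_events = max(1e8, 1000 * params$target_size)) {
  stopifnot(inherits(state, "tumor_state"), inherits(params, "sim_params"))
  n <- nrow(state$coords)
  if (params$target_size > params$lattice_extent^3)
    stop("target_size exceeds lattice capacity")
  if (params$lattice_extent != state$extent)
    stop("params lattice_extent differs from the state's lattice")
  if (params$target_size > n && params$birth_rate == 0 &&
      params$death_rate == 0)
    stop("no growth possible: birth_rate is 0 but target_size exceeds the ",
         "current population")
  if (params$target_size <= n && params$death_rate == 0) {
    state$status <- "reached"
    return(state)
  }
  res <- with_seed(params$rng_seed,
    grow_lattice(state$coords, as.integer(state$barcode),
                 params$lattice_extent, params$birth_rate, params$death_rate,
                 params$mobility, params$neighborhood,
                 params$target_size, as.numeric(max_events)))
  state$coords <- res$coords
  state$barcode <- res$barcodes
  state$n_events <- state$n_events + res$events
  state$params <- params
  state$status <- if (res$extinct) "extinct" else "reached"
  state
}

#' Convenience wrapper: seed and grow in one call
#'
#' @inheritParams initialize_tumor
#' @inheritParams grow_to
#' @return A grown `tumor_state`.
#' @export
simulate_tumor <- function(n_founders = 200, params = sim_params(), ...) {
  grow_to(initialize_tumor(n_founders, params), params, ...)
}

#' Tally cells per founder clone
#'
#' @param state A `tumor_state`.
#' @return A `clone_census`: named integer vector (names = barcode IDs,
#'   values = cell counts), covering exactly the clones still alive.
#' @export
clone_census <- function(state) {
  stopifnot(inherits(state, "tumor_state"))
  tab <- tabulate(state$barcode)
  keep <- which(tab > 0)
  structure(stats::setNames(as.integer(tab[keep]), as.character(keep)),
            population_size = nrow(state$coords),
            class = "clone_census")
}

#' @export
print.tumor_state <- function(x, ...) {
  cat("<tumor_state> ", nrow(x$coords), " cells, ",
      length(unique(x$barcode)), " clones, lattice ", x$extent, "^3, status: ",
      x$status, "\n", sep = "")
  invisible(x)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> b=", x$birth_rate, " d=", x$death_rate, " M=", x$mobility,
      " target=", x$target_size, " extent=", x$lattice_extent,
      " neighborhood=", x$neighborhood, "\n", sep = "")
  invisible(x)
}

#' @export
print.clone_census <- function(x, ...) {
  cat("<clone_census> ", length(x), " clones, ", sum(x), " cells\n", sep = "")
  invisible(x)
}

#' Export the per-cell table of a simulated tumor
#'
#' Writes one row per cell (x, y, z, barcode_id), suitable for external 3D
#' rendering.
#'
#' @param state A `tumor_state`.
#' @param path Output TSV path.
#' @export
write_cell_table <- function(state, path) {
  stopifnot(inherits(state, "tumor_state"))
  df <- data.frame(x = state$coords[, 1], y = state$coords[, 2],
                   z = state$coords[, 3], barcode_id = state$barcode)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a clone census as TSV
#'
#' @param census A `clone_census`.
#' @param path Output TSV path.
#' @export
write_census <- function(census, path) {
  df <- data.frame(barcode_id = names(census), cell_count = as.integer(census))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
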