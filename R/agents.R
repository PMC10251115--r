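#' Seed an agent population inside a disc
#'
#' Creates the individual-based population: one record per cell (id, guild,
#' mass in fmol biomass-C, continuous position in um, active flag). Cells
#' are placed uniformly at random in a disc, the standard initial condition
#' for a small dense aggregate.
#'
#' @param n_per_species cells per guild.
#' @param radius seeding disc radius, um.
#' @param center disc centre `c(x, y)`, um.
#' @param species_names character vector of guild names (order matches the
#'   scenario's species list).
#' @param m_seed initial cell mass, fmol_X (default 1).
#' @param m_div division threshold, fmol_X (default `2 * m_seed`).
#' @param m_min viability threshold, fmol_X (default `0.1 * m_seed`).
#' @param v_per_mol biomass specific volume, m^3 per mol_X (default 2.46e-4,
#'   i.e. 24.6 g/C-mol at 100 g/L dry density).
#' @param depth out-of-plane depth of the planar geometry, m (set to the
#'   grid voxel edge).
#' @param seed optional RNG seed recorded in the population; if supplied,
#'   `set.seed(seed)` is called first.
#' @return object of class `agent_population`.
#' @export
seed_population <- function(n_per_species, radius, center, species_names,
                            m_seed = 1, m_div = 2 * m_seed,
                            m_min = 0.1 * m_seed, v_per_mol = 2.46e-4,
                            depth = 2e-6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_per_species * length(species_names)
  rr <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  structure(list(
    id = seq_len(n),
    species = rep(seq_along(species_names), each = n_per_species),
    mass = rep(m_seed, n),
    x = center[1] + rr * cos(th),
    y = center[2] + rr * sin(th),
    active = rep(TRUE, n),
    next_id = n + 1L,
    removed = setNames(numeric(length(species_names)), species_names),
    washed_out = setNames(numeric(length(species_names)), species_names),
    species_names = species_names,
    params = list(m_seed = m_seed, m_div = m_div, m_min = m_min,
                  v_per_mol = v_per_mol, depth = depth),
    rng_seed = if (is.null(seed)) NA_integer_ else seed
  ), class = "agent_population")
}

#' Cell radius under the planar (unit-depth) convention
#'
#' Each cell is a disc of area `mass * v_per_mol / depth`, i.e.
#' `r = sqrt(mass * v_per_mol / (pi * depth))`.
#'
#' @param mass cell mass, fmol_X.
#' @param params the population's `params` list.
#' @return radius, um.
#' @export
cell_radius <- function(mass, params) {
  sqrt(mass * .FMOL * params$v_per_mol / (pi * params$depth)) * 1e6
}

# 0-based voxel index of a coordinate (um) on a grid with edge h (m);
# positions exactly on a voxel boundary belong to the higher voxel
# (floor-division convention).
.voxel_index <- function(coord_um, h, n) {
  i <- floor(coord_um / (h * 1e6))
  if (any(i < 0) || any(i >= n)) stop("cell position outside the grid")
  as.integer(i)
}

#' Local solute concentrations seen by each cell
#'
#' Piecewise-constant lookup: each cell reads the concentration of the voxel
#' containing its centre.
#'
#' @param pop an `agent_population`.
#' @param grid a `grid2d`.
#' @param solutes solute names to look up (default: all grid fields).
#' @return matrix, cells x solutes, uM.
#' @export
local_conc <- function(pop, grid, solutes = names(grid$conc)) {
  ix <- .voxel_index(pop$x, grid$h, grid$nx)
  iy <- .voxel_index(pop$y, grid$h, grid$ny)
  lin <- ix + 1L + ix_stride(grid) * iy
  out <- vapply(solutes, function(s) grid$conc[[s]][lin],
                numeric(length(pop$id)))
  matrix(out, nrow = length(pop$id), ncol = length(solutes),
         dimnames = list(NULL, solutes))
}

ix_stride <- function(grid) grid$nx

#' Per-cell specific growth rates from local conditions
#'
#' @param pop an `agent_population`.
#' @param grid a converged `grid2d`.
#' @param species list of [species_params()] in the population's guild order.
#' @return numeric vector of per-cell growth rates, 1/h.
#' @export
cell_growth_rates <- function(pop, grid, species) {
  lc <- local_conc(pop, grid, c("NH3", "O2"))
  mu <- numeric(length(pop$id))
  for (i in seq_along(species)) {
    sel <- pop$species == i
    if (any(sel))
      mu[sel] <- monod_growth_rate(species[[i]], lc[sel, "NH3"],
                                   lc[sel, "O2"])
  }
  mu
}

#' Grow every active cell over one time step
#'
#' Exponential update `mass <- mass * exp(mu_local * dt)` with the per-cell
#' growth rate from [cell_growth_rates()]; cells shrink where maintenance
#' exceeds local supply (mu < 0).
#'
#' @param pop an `agent_population`.
#' @param grid a converged `grid2d`.
#' @param species list of [species_params()].
#' @param dt time step, h (> 0).
#' @return the updated population.
#' @export
step_growth <- function(pop, grid, species, dt) {
  if (dt <= 0) stop("dt must be > 0")
  mu <- cell_growth_rates(pop, grid, species)
  pop$mass <- pop$mass * exp(mu * dt)
  pop
}

#' Divide cells above the division threshold
#'
#' Every cell at or above `m_div` splits into two cells of exactly half the
#' mass; the daughter receives a fresh id and is placed one centre-to-centre
#' contact distance away at a uniformly random angle. Total mass is conserved
#' exactly.
#'
#' @param pop an `agent_population`.
#' @param m_div division threshold, fmol_X (default from the population's
#'   parameters).
#' @return the updated population.
#' @export
divide_cells <- function(pop, m_div = pop$params$m_div) {
  if (m_div <= 0) stop("m_div must be > 0")
  idx <- which(pop$mass >= m_div & pop$active)
  if (!length(idx)) return(pop)
  half <- pop$mass[idx] / 2
  r <- cell_radius(half, pop$params)
  ang <- runif(length(idx), 0, 2 * pi)
  pop$mass[idx] <- half
  new_ids <- pop$next_id + seq_along(idx) - 1L
  pop$id <- c(pop$id, new_ids)
  pop$species <- c(pop$species, pop$species[idx])
  pop$mass <- c(pop$mass, half)
  pop$x <- c(pop$x, pop$x[idx] + 2 * r * cos(ang))
  pop$y <- c(pop$y, pop$y[idx] + 2 * r * sin(ang))
  pop$active <- c(pop$active, rep(TRUE, length(idx)))
  pop$next_id <- pop$next_id + length(idx)
  pop
}

#' Remove cells below the viability threshold
#'
#' Cells whose mass has decayed below `m_min` are deactivated and dropped
#' from the population; their mass is added to the per-guild `removed`
#' ledger so biomass bookkeeping stays auditable.
#'
#' @param pop an `agent_population`.
#' @param m_min viability threshold, fmol_X (default from the population's
#'   parameters).
#' @return the updated population.
#' @export
cull <- function(pop, m_min = pop$params$m_min) {
  if (m_min < 0) stop("m_min must be >= 0")
  drop <- pop$mass < m_min
  if (!any(drop)) return(pop)
  lost <- tapply(pop$mass[drop], factor(pop$species[drop],
                                        levels = seq_along(pop$species_names)),
                 sum, default = 0)
  pop$removed <- pop$removed + as.numeric(lost)
  keep <- !drop
  for (f in c("id", "species", "mass", "x", "y", "active"))
    pop[[f]] <- pop[[f]][keep]
  pop
}

#' Resolve cell overlaps by pairwise shoving
#'
#' Overlapping cell pairs are displaced apart along their centre line by
#' half the overlap each, iterating until the worst overlap is below
#' `tol_frac` of the mean cell radius or `max_iter` passes. The pair order
#' is the (ascending) id order, so the relaxation is deterministic for a
#' fixed RNG state; fully coincident centres are separated along a random
#' direction. Optionally clamps cells into a permitted disc.
#'
#' @param pop an `agent_population`.
#' @param max_iter maximum relaxation passes (default 50).
#' @param tol_frac overlap tolerance as a fraction of the mean radius
#'   (default 0.01).
#' @param r_max optional permitted radius, um: cells are pulled back inside
#'   the disc of this radius around `center` after relaxation.
#' @param center permitted-disc centre `c(x, y)`, um.
#' @return the updated population (masses untouched).
#' @export
shove <- function(pop, max_iter = 50, tol_frac = 0.01, r_max = NULL,
                  center = NULL) {
  if (length(pop$id) < 2) return(pop)
  r <- cell_radius(pop$mass, pop$params)
  ans <- shove_cpp(pop$x, pop$y, r, as.integer(max_iter), tol_frac)
  pop$x <- ans$x; pop$y <- ans$y
  if (!is.null(r_max)) {
    dx <- pop$x - center[1]; dy <- pop$y - center[2]
    d <- sqrt(dx^2 + dy^2)
    lim <- pmax(r_max - r, 0)
    out <- d > lim & d > 0
    if (any(out)) {
      f <- lim[out] / d[out]
      pop$x[out] <- center[1] + dx[out] * f
      pop$y[out] <- center[2] + dy[out] * f
    }
  }
  pop
}

#' Wash out cells at the reactor dilution rate
#'
#' The simulated aggregate is representative of suspended aggregates in the
#' reactor, which leave with the effluent. Each cell is removed with
#' probability `1 - exp(-dt / HRT)` per step (independent Bernoulli draws);
#' removed mass accumulates in the per-guild `washed_out` ledger.
#'
#' @param pop an `agent_population`.
#' @param dt macro time step, h.
#' @param HRT hydraulic retention time, h.
#' @return the updated population.
#' @export
dilute_population <- function(pop, dt, HRT) {
  n <- length(pop$id)
  if (!n) return(pop)
  gone <- runif(n) < (1 - exp(-dt / HRT))
  if (!any(gone)) return(pop)
  lost <- tapply(pop$mass[gone],
                 factor(pop$species[gone],
                        levels = seq_along(pop$species_names)),
                 sum, default = 0)
  pop$washed_out <- pop$washed_out + as.numeric(lost)
  keep <- !gone
  for (f in c("id", "species", "mass", "x", "y", "active"))
    pop[[f]] <- pop[[f]][keep]
  pop
}

#' Map individual cell activity onto the voxel reaction field
#'
#' Each voxel's volumetric rate is the sum over the cells it contains:
#' `R_xy = stoich * sum (1/Y) max(mu_local, 0) mass / voxel volume`, in
#' uM/h (NH3 negative, products positive). Rates are zero outside occupied
#' voxels, hence zero outside aggregate voxels once the aggregate mask
#' includes every occupied voxel.
#'
#' @param pop an `agent_population`.
#' @param grid a `grid2d` with current concentration fields.
#' @param species list of [species_params()].
#' @return a [reaction_field()] with attribute `uptake_by_species`
#'   (umol N/h per guild, whole grid).
#' @export
cells_to_reaction_field <- function(pop, grid, species) {
  R <- reaction_field(grid)
  uptake <- setNames(numeric(length(species)), pop$species_names)
  n <- length(pop$id)
  if (!n) {
    attr(R, "uptake_by_species") <- uptake
    return(R)
  }
  mu <- cell_growth_rates(pop, grid, species)
  ix <- .voxel_index(pop$x, grid$h, grid$nx)
  iy <- .voxel_index(pop$y, grid$h, grid$ny)
  lin <- ix + 1L + grid$nx * iy
  vox_L <- grid$h^3 * 1000  # voxel volume in litres (unit depth h)
  for (i in seq_along(species)) {
    sel <- pop$species == i & pop$active
    if (!any(sel)) next
    # umol N oxidized per hour per cell
    u <- (1 / species[[i]]$yield) * pmax(mu[sel], 0) *
      pop$mass[sel] * .FMOL * 1e6
    uptake[i] <- sum(u)
    agg <- rowsum(u, lin[sel])
    vox <- as.integer(rownames(agg))
    for (s in names(species[[i]]$stoich)) {
      st <- species[[i]]$stoich[[s]]
      if (st != 0 && s %in% names(R))
        R[[s]][vox] <- R[[s]][vox] + st * agg[, 1] / vox_L
    }
  }
  attr(R, "uptake_by_species") <- uptake
  R
}

#' @export
print.agent_population <- function(x, ...) {
  cat(sprintf("<agent_population> %d cells (%s)\n", length(x$id),
              paste(sprintf("%s %d", x$species_names,
                            tabulate(x$species, length(x$species_names))),
                    collapse = ", ")))
  cat(sprintf("  total mass %.3g fmol_X; culled %.3g; washed out %.3g\n",
              sum(x$mass), sum(x$removed), sum(x$washed_out)))
  invisible(x)
}
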