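# region labels for Grid2D voxels
REGION <- c(aggregate = 1L, boundary_layer = 2L, bulk_edge = 3L)

#' Low-level 2-D voxel grid constructor
#'
#' Builds a labelled voxel grid with per-solute concentration fields. Most
#' users want [build_grid()], which lays out the standard circular
#' aggregate + boundary-layer geometry; this constructor accepts an
#' arbitrary region labelling (e.g. a 1-D slab for verification problems).
#'
#' @param nx,ny voxel counts (matrix is `nx` rows by `ny` columns; x runs
#'   along rows). Voxel indices are 0-based with voxel-centred coordinates
#'   `(i + 0.5) h`.
#' @param h voxel edge length, m (> 0). The grid is planar with unit depth
#'   `h` (each voxel represents a volume `h^3`).
#' @param region integer `nx` x `ny` matrix of labels: 1 aggregate,
#'   2 boundary layer, 3 bulk edge (Dirichlet at the bulk concentration).
#' @param bulk_conc named per-solute bulk concentrations, uM; fields are
#'   initialized uniformly at these values.
#' @param hindrance factor applied to diffusion coefficients inside
#'   aggregate voxels (biofilm matrix hindrance; default 0.5).
#' @return object of class `grid2d`.
#' @export
grid2d <- function(nx, ny, h, region, bulk_conc, hindrance = 0.5) {
  if (h <= 0) stop("voxel edge length h must be > 0")
  stopifnot(nrow(region) == nx, ncol(region) == ny)
  conc <- lapply(bulk_conc, function(v) matrix(v, nx, ny))
  structure(list(nx = nx, ny = ny, h = h, region = region, conc = conc,
                 bulk_conc = bulk_conc, hindrance = hindrance),
            class = "grid2d")
}

#' Build the standard aggregate + boundary-layer grid
#'
#' A circular aggregate of the given radius is centred in the domain,
#' surrounded by a diffusive boundary-layer annulus; all voxels beyond the
#' annulus (including the outer frame) are bulk-edge voxels held at the bulk
#' concentration. Voxel centres at `(i + 0.5) h` decide membership.
#'
#' @inheritParams grid2d
#' @param aggregate_radius aggregate radius, m (0 gives no aggregate voxels).
#' @param boundary_layer boundary-layer thickness, m.
#' @param bulk_conc named per-solute bulk concentrations, uM.
#' @return object of class `grid2d`.
#' @examples
#' g <- build_grid(50, 50, h = 2e-6, aggregate_radius = 2e-5,
#'                 boundary_layer = 1e-5, bulk_conc = c(NH3 = 200, O2 = 100))
#' table(g$region)
#' @export
build_grid <- function(nx, ny, h, aggregate_radius, boundary_layer,
                       bulk_conc, hindrance = 0.5) {
  if (h <= 0) stop("voxel edge length h must be > 0")
  half <- (min(nx, ny) / 2 - 1) * h  # frame must stay bulk edge
  if (aggregate_radius + boundary_layer > half)
    stop("geometry overflow: aggregate + boundary layer does not fit ",
         "inside the grid (needs radius + thickness <= ",
         format(half), " m)")
  cx <- nx * h / 2; cy <- ny * h / 2
  xs <- (seq_len(nx) - 0.5) * h
  ys <- (seq_len(ny) - 0.5) * h
  dist <- sqrt(outer((xs - cx)^2, (ys - cy)^2, `+`))
  region <- matrix(REGION[["bulk_edge"]], nx, ny)
  region[dist <= aggregate_radius + boundary_layer] <- REGION[["boundary_layer"]]
  region[dist <= aggregate_radius] <- REGION[["aggregate"]]
  region[c(1, nx), ] <- REGION[["bulk_edge"]]
  region[, c(1, ny)] <- REGION[["bulk_edge"]]
  grid2d(nx, ny, h, region, bulk_conc, hindrance)
}

#' Empty per-solute reaction field on a grid
#'
#' @param grid a `grid2d`.
#' @return object of class `reaction_field`: named list of `nx` x `ny`
#'   matrices of volumetric rates, uM/h (signed; zero outside aggregate
#'   voxels by construction of [cells_to_reaction_field()]).
#' @export
reaction_field <- function(grid) {
  structure(lapply(grid$conc, function(m) matrix(0, grid$nx, grid$ny)),
            class = "reaction_field")
}

#' Discrete Laplacian on a voxel field
#'
#' Standard 5-point stencil `(N + S + E + W - 4C) / h^2`. Array edges
#' without a neighbour are treated as no-flux (mirror). If a region
#' labelling is supplied, bulk-edge voxels are Dirichlet values: their
#' entry in the result is 0 (they are never updated).
#'
#' @param field numeric matrix.
#' @param h voxel edge length, m.
#' @param region optional region label matrix (see [grid2d()]).
#' @return matrix of the same shape.
#' @export
grid_laplacian <- function(field, h, region = NULL) {
  nr <- nrow(field); nc <- ncol(field)
  up    <- field[c(1, seq_len(nr - 1)), , drop = FALSE]
  down  <- field[c(seq_len(nr - 1) + 1, nr), , drop = FALSE]
  left  <- field[, c(1, seq_len(nc - 1)), drop = FALSE]
  right <- field[, c(seq_len(nc - 1) + 1, nc), drop = FALSE]
  lap <- (up + down + left + right - 4 * field) / h^2
  if (!is.null(region)) lap[region == REGION[["bulk_edge"]]] <- 0
  lap
}

#' Pseudo-steady-state reaction--diffusion solve
#'
#' For each solute, solves the stationary limit of
#' `d[S]/dt = D lap [S] + R` on the grid: bulk-edge voxels are Dirichlet
#' boundaries at `bulk_conc`, diffusion inside aggregate voxels is slowed by
#' the grid's hindrance factor, and the interior residual
#' `|D lap S + R|` is driven below `tol * max(|R|, floor)`. Concentrations
#' are kept non-negative; voxels pinned at zero (reaction demand exceeding
#' diffusive supply) are counted in the `clipping` attribute.
#'
#' Optionally the reaction may be passed in linearized form
#' `R = source - kappa * S` (`kappa >= 0`), which is how the multiscale
#' coupler iterates Monod rates to co-convergence; the fixed-rate call is
#' the `kappa = NULL` case.
#'
#' @param grid a `grid2d`; its `conc` fields are the initial guess.
#' @param D named per-solute diffusion coefficients, m^2/h (only the named
#'   solutes are solved).
#' @param R a [reaction_field()] (volumetric rates, uM/h).
#' @param bulk_conc named per-solute bulk concentrations, uM.
#' @param tol relative residual tolerance (default 1e-6).
#' @param kappa optional named list of per-voxel first-order consumption
#'   coefficients, 1/h.
#' @param omega SOR over-relaxation factor (default 1.9).
#' @param max_iter maximum SOR sweeps per solute.
#' @param res_floor absolute floor of the residual scale, uM/h.
#' @param on_fail `"error"` (default) aborts with a residual report on
#'   non-convergence; `"warn"` continues.
#' @return the grid with converged `conc`, with attributes `pss_iterations`,
#'   `pss_residual`, `clipping` (named per solute).
#' @export
solve_pss <- function(grid, D, R, bulk_conc, tol = 1e-6, kappa = NULL,
                      omega = 1.9, max_iter = 50000, res_floor = 1e-10,
                      on_fail = c("error", "warn")) {
  on_fail <- match.arg(on_fail)
  if (any(D <= 0)) stop("diffusion coefficients must be > 0")
  if (any(bulk_conc[names(D)] < 0)) stop("bulk concentrations must be >= 0")
  dir_mask <- grid$region == REGION[["bulk_edge"]]
  hind <- ifelse(grid$region == REGION[["aggregate"]], grid$hindrance, 1)
  iters <- resid <- clipped <- setNames(numeric(length(D)), names(D))
  for (s in names(D)) {
    Dm <- D[[s]] * hind
    c0 <- grid$conc[[s]]
    c0[dir_mask] <- bulk_conc[[s]]
    kap <- if (is.null(kappa)) matrix(0, grid$nx, grid$ny) else kappa[[s]]
    ans <- sor_pss_cpp(c0, Dm, kap, R[[s]], dir_mask, grid$h, omega, tol,
                       as.integer(max_iter), TRUE, res_floor)
    if (!ans$converged) {
      msg <- sprintf(
        "pseudo-steady solve for %s did not converge in %d sweeps (residual %.3g, tolerance %.3g)",
        s, ans$iterations, ans$residual, tol * ans$scale)
      if (on_fail == "error") stop(msg) else warning(msg)
    }
    grid$conc[[s]] <- ans$conc
    iters[s] <- ans$iterations; resid[s] <- ans$residual
    clipped[s] <- ans$clipped
  }
  attr(grid, "pss_iterations") <- iters
  attr(grid, "pss_residual") <- resid
  attr(grid, "clipping") <- clipped
  grid
}

#' @export
print.grid2d <- function(x, ...) {
  counts <- table(factor(x$region, levels = REGION,
                         labels = names(REGION)))
  cat(sprintf("<grid2d> %d x %d voxels, h = %g m (%.0f x %.0f um)\n",
              x$nx, x$ny, x$h, x$nx * x$h * 1e6, x$ny * x$h * 1e6))
  cat("  regions:", paste(sprintf("%s %d", names(counts), counts),
                          collapse = ", "), "\n")
  cat("  solutes:", paste(names(x$conc), collapse = ", "), "\n")
  invisible(x)
}

#' Heat-map of one solute field
#'
#' @param x a `grid2d`.
#' @param solute solute name (default first field).
#' @param ... passed to [graphics::image()].
#' @export
plot.grid2d <- function(x, solute = names(x$conc)[1], ...) {
  xs <- (seq_len(x$nx) - 0.5) * x$h * 1e6
  ys <- (seq_len(x$ny) - 0.5) * x$h * 1e6
  graphics::image(xs, ys, x$conc[[solute]], col = grDevices::hcl.colors(64),
                  xlab = "x (um)", ylab = "y (um)",
                  main = sprintf("%s (uM)", solute), useRaster = TRUE, ...)
  invisible(x)
}

#' Per-voxel CSV dump of a grid
#'
#' Long-format export (one row per voxel: 0-based indices, centre
#' coordinates in um, region label, one column per solute, uM) for
#' inspection of small grids.
#'
#' @param grid a `grid2d`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  ix <- rep(seq_len(grid$nx) - 1L, grid$ny)
  iy <- rep(seq_len(grid$ny) - 1L, each = grid$nx)
  df <- data.frame(
    ix = ix, iy = iy,
    x_um = (ix + 0.5) * grid$h * 1e6,
    y_um = (iy + 0.5) * grid$h * 1e6,
    region = names(REGION)[as.vector(grid$region)])
  for (s in names(grid$conc)) df[[s]] <- as.vector(grid$conc[[s]])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
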