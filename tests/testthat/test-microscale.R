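test_that("grid builder lays out aggregate, boundary layer and bulk edge geometry", {
  bc <- c(NH3 = 200, O2 = 100)
  g0 <- build_grid(50, 50, 2e-6, 0, 1e-5, bc)
  expect_equal(sum(g0$region == 1L), 0)
  expect_error(build_grid(50, 50, 2e-6, 5e-5, 1e-5, bc), "overflow")
  # 100x100 voxels of 2 um, 50 um radius: ~ pi * 25^2 voxel centres inside
  g <- build_grid(100, 100, 2e-6, 5e-5, 2e-5, bc)
  n_agg <- sum(g$region == 1L)
  expect_lt(abs(n_agg - pi * 25^2), 40)
  # outer frame is always bulk edge
  expect_true(all(g$region[c(1, 100), ] == 3L))
  expect_true(all(g$region[, c(1, 100)] == 3L))
  # fields initialized at bulk values
  expect_true(all(g$conc$NH3 == 200))
})

test_that("discrete Laplacian is exact on constants, quadratics and point sources", {
  h <- 2e-6
  f <- matrix(7, 20, 20)
  expect_equal(grid_laplacian(f, h), matrix(0, 20, 20))
  # f = x^2 at voxel centres: interior stencil value exactly 2
  xs <- ((seq_len(20)) - 0.5) * h
  fx <- matrix(xs^2, 20, 20)
  lap <- grid_laplacian(fx, h)
  expect_equal(lap[2:19, 2:19], matrix(2, 18, 18), tolerance = 1e-9)
  # single interior spike
  sp <- matrix(0, 9, 9); sp[5, 5] <- 3
  lap <- grid_laplacian(sp, h)
  expect_equal(lap[5, 5], -4 * 3 / h^2)
  expect_equal(lap[4, 5], 3 / h^2)
  expect_equal(lap[5, 6], 3 / h^2)
  # bulk-edge voxels are held (not updated)
  region <- matrix(1L, 9, 9); region[1, ] <- 3L
  expect_equal(grid_laplacian(sp, h, region)[1, ], rep(0, 9))
})

test_that("zero reaction relaxes every voxel to the bulk concentration", {
  g <- build_grid(30, 30, 2e-6, 1e-5, 8e-6, c(S = 42), hindrance = 1)
  g$conc$S <- matrix(runif(900, 0, 100), 30, 30)  # arbitrary start
  g2 <- solve_pss(g, c(S = 5.5e-6), reaction_field(g), c(S = 42), tol = 1e-8)
  expect_equal(g2$conc$S, matrix(42, 30, 30), tolerance = 1e-6)
})

test_that("slab with constant sink matches C(x) = C0 - q x (L - x) / (2D) and refines at O(h^2)", {
  C0 <- 10; D <- c(S = 5.5e-6)
  err_for <- function(nx, q) {
    g <- slab_grid(nx, C0)
    R <- reaction_field(g)
    R$S[g$region == 1L] <- -q
    g2 <- solve_pss(g, D, R, c(S = C0), tol = 1e-8)
    xs <- (seq_len(nx) - 0.5) * g$h
    xl <- 0.5 * g$h; xr <- (nx - 0.5) * g$h
    ana <- C0 - q * (xs - xl) * (xr - xs) / (2 * D[["S"]])
    max(abs(g2$conc$S[2:(nx - 1), 2] - ana[2:(nx - 1)])) / C0
  }
  # h = L/52 < L/50
  expect_lt(err_for(52, 2e4), 1e-3)
  # halving h does not worsen the solution (stencil is exact on quadratics,
  # so both errors sit at solver tolerance)
  expect_lte(err_for(104, 5e3), max(err_for(52, 5e3), 1e-6))
})

test_that("pseudo-steady solver agrees with brute-force explicit time stepping", {
  # independent oracle: integrate dC/dt = D lap C + R to stationarity
  set.seed(7)
  nx <- 10; h <- 2e-6; D <- 5.5e-6; C0 <- 20
  region <- matrix(1L, nx, nx)
  region[c(1, nx), ] <- 3L; region[, c(1, nx)] <- 3L
  g <- grid2d(nx, nx, h, region, c(S = C0), hindrance = 1)
  R <- reaction_field(g)
  R$S[region == 1L] <- -runif(sum(region == 1L), 0, 3e4)
  field <- matrix(C0, nx, nx)
  dt <- 0.2 * h^2 / (4 * D)
  for (i in 1:20000) {
    lap <- grid_laplacian(field, h, region)
    field <- field + dt * (D * lap + R$S)
    field[region == 3L] <- C0
  }
  g2 <- solve_pss(g, c(S = D), R, c(S = C0), tol = 1e-9)
  expect_equal(g2$conc$S, field, tolerance = 1e-5)
})

test_that("pure consumption obeys the maximum principle and boundary-flux balance", {
  g <- build_grid(40, 40, 2e-6, 2e-5, 1e-5, c(S = 50), hindrance = 1)
  R <- reaction_field(g)
  R$S[g$region == 1L] <- -5e4
  g2 <- solve_pss(g, c(S = 5.5e-6), R, c(S = 50), tol = 1e-8)
  inner <- g2$conc$S[g2$region != 3L]
  expect_true(all(inner <= 50 + 1e-9))
  expect_gte(min(inner), 0)
  # flux balance: diffusive influx through the Dirichlet frontier equals
  # total consumption (no clipping at this sink strength)
  expect_equal(attr(g2, "clipping")[["S"]], 0)
  f <- g2$conc$S; region <- g2$region; h <- g2$h
  influx <- 0
  for (i in 2:39) for (j in 2:39) {
    if (region[i, j] == 3L) next
    for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
      if (region[nb[1], nb[2]] == 3L)
        influx <- influx + 5.5e-6 * (f[nb[1], nb[2]] - f[i, j]) / h^2
    }
  }
  consumption <- -sum(R$S)
  expect_equal(influx, consumption, tolerance = 1e-5)
})

test_that("pseudo-steady solution is independent of the initial guess", {
  g <- build_grid(30, 30, 2e-6, 1.5e-5, 6e-6, c(S = 30), hindrance = 1)
  R <- reaction_field(g)
  R$S[g$region == 1L] <- -2e4
  sol1 <- solve_pss(g, c(S = 5.5e-6), R, c(S = 30), tol = 1e-9)
  g$conc$S <- matrix(runif(900, 0, 60), 30, 30)
  sol2 <- solve_pss(g, c(S = 5.5e-6), R, c(S = 30), tol = 1e-9)
  expect_equal(sol1$conc$S, sol2$conc$S, tolerance = 1e-6)
})

test_that("infeasible reaction demand is clipped at zero and reported", {
  g <- slab_grid(40, C0 = 5)
  R <- reaction_field(g)
  R$S[g$region == 1L] <- -5e6  # far beyond diffusive supply
  g2 <- solve_pss(g, c(S = 5.5e-6), R, c(S = 5), tol = 1e-6)
  expect_gt(attr(g2, "clipping")[["S"]], 0)
  expect_gte(min(g2$conc$S), 0)
})
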