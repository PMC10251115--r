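test_that("representative-volume scale-up reduces to closed-form arithmetic", {
  g <- build_grid(20, 20, 2e-6, 8e-6, 4e-6, c(NH3 = 10, O2 = 100))
  spec <- coupling_spec(reactor_volume = 2, n_aggregates = 1e5)
  R <- reaction_field(g)
  expect_equal(unname(scale_up_rates(R, g, spec)), c(0, 0))
  R$NH3[g$region == 1L] <- -3e4
  k <- sum(g$region == 1L)
  expect_equal(scale_up_rates(R, g, spec)[["NH3"]],
               -3e4 * k * (2e-6)^3 * 1000 * 1e5 / 2)
})

test_that("scaled-up rate equals the diffusive boundary influx of the converged field", {
  # Fick-flux oracle: with one aggregate per litre the reactor-basis rate
  # must equal the flux through the Dirichlet frontier
  g <- build_grid(40, 40, 2e-6, 2e-5, 1e-5, c(NH3 = 50, O2 = 100),
                  hindrance = 1)
  R <- reaction_field(g)
  R$NH3[g$region == 1L] <- -4e4
  g2 <- solve_pss(g, c(NH3 = 5.5e-6), R, c(NH3 = 50), tol = 1e-8)
  spec <- coupling_spec(reactor_volume = 1, n_aggregates = 1)
  r_bl <- scale_up_rates(R, g2, spec)[["NH3"]]
  f <- g2$conc$NH3; region <- g2$region; h <- g2$h
  influx <- 0
  for (i in 2:39) for (j in 2:39) {
    if (region[i, j] == 3L) next
    for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1)))
      if (region[nb[1], nb[2]] == 3L)
        influx <- influx + 5.5e-6 * (f[nb[1], nb[2]] - f[i, j]) / h^2
  }
  influx_reactor <- influx * h^3 * 1000 / 1   # uM/h on the reactor basis
  expect_equal(r_bl, -influx_reactor, tolerance = 1e-5)
})

test_that("macro step reproduces the linear CSTR closed forms", {
  spec <- single_species_spec(HRT = 240)
  bulk <- spec$influent
  # R_BL = 0 at influent concentrations: fixed point
  s1 <- macro_step(bulk, c(NH3 = 0, O2 = 0, NO2 = 0, NO3 = 0), spec, 1)
  expect_equal(as.numeric(s1), unname(bulk))
  # R_BL = 0: exponential relaxation toward the influent
  b2 <- c(NH3 = 10, O2 = 100, NO2 = 40, NO3 = 0)
  s2 <- macro_step(b2, c(NH3 = 0, O2 = 0, NO2 = 0, NO3 = 0), spec, 24)
  expect_equal(s2[["NH3"]], 200 + (10 - 200) * exp(-24 / 240))
  expect_equal(s2[["NO2"]], 40 * exp(-24 / 240))
  # constant consumption settles at S_inf + HRT * R_BL
  rbl <- c(NH3 = -0.5, O2 = 0, NO2 = 0.5, NO3 = 0)
  s <- bulk
  for (i in 1:100) s <- setNames(as.numeric(macro_step(s, rbl, spec, 50)),
                                 names(bulk))
  expect_equal(s[["NH3"]], 200 + 240 * (-0.5), tolerance = 1e-6)
  # driving the bulk negative is a coupling error
  expect_error(macro_step(bulk, c(NH3 = -10, O2 = 0, NO2 = 0, NO3 = 0),
                          spec, 200), "instability")
})

test_that("dilution bookkeeping of the macro step is exact", {
  spec <- single_species_spec(HRT = 240)
  b <- c(NH3 = 120, O2 = 100, NO2 = 10, NO3 = 5)
  rbl <- c(NH3 = -0.3, O2 = -0.45, NO2 = 0.3, NO3 = 0)
  s <- macro_step(b, rbl, spec, 1)
  dil <- attr(s, "dilution_exchange")
  expect_equal(s[["NH3"]] - b[["NH3"]], dil[["NH3"]] + rbl[["NH3"]] * 1)
})

test_that("an empty reactor relaxes to the influent with no reaction", {
  sc <- mini_ibm_scenario(t_end_d = 10)
  sc$agents$n_cells_per_species <- 0L
  sc$chemostat$initial_solutes[["NH3"]] <- 20
  res <- run_multiscale(sc, seed = 4)
  tr <- res$trajectory
  s_in <- sc$chemostat$influent[["NH3"]]
  # pure dilution: S(t) = S_inf - (S_inf - S_0) exp(-t/HRT)
  expect_equal(unname(tr$solutes[nrow(tr$solutes), "NH3"]),
               s_in - (s_in - 20) * exp(-240 / 240), tolerance = 1e-9)
  expect_true(all(tr$n_cells == 0))
  expect_true(all(is.na(res$weight_fractions)))
  expect_error(weight_fractions(res$final_biomass), "undefined")
})

test_that("fixed-boundary single-cell run reduces to the exponential growth closed form", {
  sc <- mini_ibm_scenario(t_end_d = 10, boundary_mode = "fixed")
  sc$agents$n_cells_per_species <- 1L
  sc$agents$seed_radius_um <- 1
  sc$agents$m_div_fmol <- 1e9   # suppress division for the closed form
  sc$chemostat$initial_solutes[c("NH3", "O2")] <- c(1e9, 1e9)  # saturating
  sc$solutes$influent[c("NH3", "O2")] <- c(1e9, 1e9)
  sc$chemostat$influent <- sc$solutes$influent
  res <- run_multiscale(sc, seed = 2)
  tr <- res$trajectory
  m_ratio <- tr$biomass[nrow(tr$biomass), ] / tr$biomass[1, ]
  expect_equal(unname(m_ratio), rep(exp(0.009 * 240), 2), tolerance = 1e-3)
  # fixed mode: bulk never moves
  expect_true(all(tr$solutes[, "NH3"] == 1e9))
})

test_that("coupled runs are bit-reproducible for a fixed seed and differ across seeds", {
  sc <- mini_ibm_scenario(t_end_d = 5)
  r1 <- run_multiscale(sc, seed = 42)
  r2 <- run_multiscale(sc, seed = 42)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$population, r2$population)
  r3 <- run_multiscale(sc, seed = 43)
  expect_false(identical(r1$trajectory$biomass, r3$trajectory$biomass))
  expect_identical(r1$provenance$config_hash, r3$provenance$config_hash)
})

test_that("replicate summary statistics follow their definitions", {
  sc <- mini_ibm_scenario(t_end_d = 2)
  reps <- replicate_runs(sc, seeds = c(7, 7, 8))
  expect_equal(reps$weight_fractions[1, ], reps$weight_fractions[2, ])
  expect_equal(unname(reps$mean),
               unname(colMeans(reps$weight_fractions)))
  one <- replicate_runs(sc, seeds = 7)
  expect_equal(unname(one$mean), unname(one$weight_fractions[1, ]))
  expect_error(replicate_runs(sc, seeds = integer(0)), "seed")
})

test_that("the coupled model closes its nitrogen balance", {
  sc <- mini_ibm_scenario(t_end_d = 20)
  res <- run_multiscale(sc, seed = 1)
  expect_lt(res$n_balance_rel_error, 1e-3)
  # products appear in the bulk as ammonia is consumed
  tr <- res$trajectory
  expect_gt(tr$solutes[nrow(tr$solutes), "NO3"], 0)
})

test_that("fused and damped-Picard micro solvers agree on the same fixed point", {
  species <- list(ao_params(), cmx_params())
  g <- build_grid(40, 40, 2e-6, 1.5e-5, 1e-5,
                  c(NH3 = 30, O2 = 100, NO2 = 0, NO3 = 0))
  g$D <- c(NH3 = 5.5e-6, O2 = 7.2e-6)
  set.seed(14)
  pop <- seed_population(20, 12, c(40, 40), c("AO", "CMX"), depth = 2e-6)
  bulk <- c(NH3 = 30, O2 = 100, NO2 = 0, NO3 = 0)
  m1 <- solve_microenv(pop, g, species, bulk, method = "fused")
  m2 <- solve_microenv(pop, g, species, bulk, method = "picard")
  expect_equal(m1$grid$conc$NH3, m2$grid$conc$NH3, tolerance = 1e-3)
  expect_equal(sum(m1$R$NH3), sum(m2$R$NH3), tolerance = 1e-4)
})
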