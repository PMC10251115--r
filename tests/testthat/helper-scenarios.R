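# shared fixtures, all built in code

# the canonical ammonia-oxidizer parameter set of the packaged scenario
ao_params <- function(yield = 4.09e-2) {
  species_params("AO", mu_max = 0.01, K_NH3 = 1.0, K_O2 = 3.13,
                 a_m = 0.001, yield = yield,
                 stoich = c(NH3 = -1, O2 = -1.5, NO2 = 1, NO3 = 0))
}

cmx_params <- function(yield = 6.51e-2) {
  species_params("CMX", mu_max = 0.01, K_NH3 = 1.0, K_O2 = 3.13,
                 a_m = 0.001, yield = yield,
                 stoich = c(NH3 = -1, O2 = -2, NO2 = 0, NO3 = 1))
}

four_solutes <- function() {
  solute_set(c("NH3", "O2", "NO2", "NO3"),
             diffusion = c(NH3 = 5.5e-6, O2 = 7.2e-6, NO2 = 4.5e-6,
                           NO3 = 4.5e-6),
             influent = c(NH3 = 200, O2 = 100, NO2 = 0, NO3 = 0))
}

# single-guild chemostat spec with O2 held non-limiting
single_species_spec <- function(HRT = 240, t_end = 20000, nh3_in = 200,
                                X0 = 1e-7) {
  chemostat_spec(HRT = HRT,
                 influent = c(NH3 = nh3_in, O2 = 100, NO2 = 0, NO3 = 0),
                 initial_solutes = c(NH3 = nh3_in, O2 = 100, NO2 = 0,
                                     NO3 = 0),
                 initial_biomass = c(AO = X0),
                 t_end = t_end, o2_mode = "held", o2_value = 100)
}

# 1-D slab grid: left/right columns Dirichlet, interior rows no-flux
slab_grid <- function(nx, C0 = 10, h = 2e-6, ny = 3) {
  region <- matrix(REGION_AGGREGATE(), nx, ny)
  region[c(1, nx), ] <- REGION_BULK_EDGE()
  grid2d(nx, ny, h, region, bulk_conc = c(S = C0), hindrance = 1)
}
REGION_AGGREGATE <- function() 1L
REGION_BOUNDARY <- function() 2L
REGION_BULK_EDGE <- function() 3L

# down-scaled coupled scenario for directional / property experiments:
# 60x60 grid, 20 um aggregate and boundary layer, 25 cells per guild,
# influent lowered to 50 uM NH3 so the bulk becomes ammonia-limited within
# weeks at one aggregate per microlitre
mini_ibm_scenario <- function(t_end_d = 60, boundary_mode = "dynamic") {
  sc <- comammox_scenario(mode = "ibm", t_end_d = t_end_d,
                          boundary_mode = boundary_mode)
  sc$grid <- list(nx = 60L, ny = 60L, h_m = 2e-6,
                  aggregate_radius_m = 2e-5, boundary_layer_m = 2e-5,
                  hindrance = 0.5)
  sc$agents$n_cells_per_species <- 25L
  sc$agents$seed_radius_um <- 20
  sc$solutes$influent[["NH3"]] <- 50
  sc$chemostat$influent <- sc$solutes$influent
  sc$chemostat$initial_solutes <- sc$solutes$influent
  sc$coupling <- coupling_spec(boundary_mode = boundary_mode,
                               reactor_volume = 1, n_aggregates = 1e6,
                               dt_macro = 1)
  sc
}

# population of n cells at given positions (um), single guild by default
make_pop <- function(x, y, mass = 1, species = 1L,
                     species_names = c("AO", "CMX"), depth = 2e-6) {
  n <- length(x)
  pop <- seed_population(1, 1, c(0, 0), species_names, depth = depth)
  pop$id <- seq_len(n)
  pop$species <- rep_len(as.integer(species), n)
  pop$mass <- rep_len(mass, n)
  pop$x <- x; pop$y <- y
  pop$active <- rep(TRUE, n)
  pop$next_id <- n + 1L
  pop
}
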