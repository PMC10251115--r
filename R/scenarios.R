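#' The packaged comammox vs canonical ammonia-oxidizer scenario
#'
#' Two nitrifying guilds compete for ammonia in a chemostat: a canonical
#' ammonia oxidizer (`AO`, NH3 -> NO2-) and a complete ammonia oxidizer
#' (`CMX`, comammox, NH3 -> NO3-). They share identical growth kinetics
#' (mu_max 0.01 1/h, K_NH3 1.0 uM, K_O2 3.13 uM, maintenance 0.001 1/h) —
#' no kinetic competition — and differ only in growth yield: 4.09e-2 vs
#' 6.51e-2 mol_X/mol_N. The reactor runs ammonia-limited (influent 200 uM
#' NH3, HRT 240 h, i.e. dilution 0.0042 1/h, safely below the washout bound
#' mu_max - a_m = 0.009 1/h) with bulk O2 held non-limiting at 100 uM.
#' Default horizon 1825 d. The IbM sections seed 50 cells per guild in a
#' 40 um disc on a 100 x 100 grid of 2 um voxels with a 40 um boundary
#' layer, one simulated aggregate representing 1e6 aggregates in 1 L.
#'
#' @param mode `"ode"` (well-mixed Model 1) or `"ibm"` (coupled Model 2).
#' @param t_end_d simulated horizon, days (default 1825).
#' @param boundary_mode coupling boundary mode for `"ibm"` (default
#'   `"dynamic"`).
#' @param seeds RNG seeds for replicate IbM runs (default 1:3).
#' @return object of class `aggsim_scenario`.
#' @examples
#' sc <- comammox_scenario()
#' vapply(sc$species, function(s) s$yield, 0)
#' @export
comammox_scenario <- function(mode = c("ode", "ibm"), t_end_d = 1825,
                              boundary_mode = "dynamic", seeds = 1:3) {
  mode <- match.arg(mode)
  sol <- solute_set(
    c("NH3", "O2", "NO2", "NO3"),
    diffusion = c(NH3 = 5.5e-6, O2 = 7.2e-6, NO2 = 4.5e-6, NO3 = 4.5e-6),
    influent  = c(NH3 = 200, O2 = 100, NO2 = 0, NO3 = 0))
  species <- list(
    species_params("AO",  mu_max = 0.01, K_NH3 = 1.0, K_O2 = 3.13,
                   a_m = 0.001, yield = 4.09e-2,
                   stoich = c(NH3 = -1, O2 = -1.5, NO2 = 1, NO3 = 0)),
    species_params("CMX", mu_max = 0.01, K_NH3 = 1.0, K_O2 = 3.13,
                   a_m = 0.001, yield = 6.51e-2,
                   stoich = c(NH3 = -1, O2 = -2, NO2 = 0, NO3 = 1)))
  chem <- chemostat_spec(
    HRT = 240,
    influent = sol$influent,
    initial_solutes = sol$influent,
    initial_biomass = c(AO = 5e-8, CMX = 5e-8),
    t_end = t_end_d * 24,
    o2_mode = "held", o2_value = 100)
  card <- model_card(
    domain = paste("Nitrifying community in a continuous stirred tank",
                   "reactor run to steady state; biomass grows as small",
                   "dense aggregates suspended in the bulk liquid."),
    question = paste("Can complete ammonia oxidizers (comammox) be",
                     "selected over canonical ammonia oxidizers under",
                     "ammonia limitation?"),
    interpretation = paste("Model 1 neglects intra-aggregate diffusion",
                           "gradients (well-mixed); Model 2 resolves",
                           "individual cells, an aggregate + boundary",
                           "layer micro-scale and the bulk macro-scale."),
    assumptions = paste("Identical growth kinetics for both guilds (no",
                        "kinetic competition); different growth yields;",
                        "ideal CSTR behaviour; O2 held non-limiting."),
    formalism = paste("Dual-Monod growth with maintenance; CSTR mass",
                      "balances; 2-D reaction-diffusion at pseudo-steady",
                      "state coupled by representative-volume scale-up."))
  structure(list(
    model_card = card,
    solutes = sol,
    species = species,
    chemostat = chem,
    grid = list(nx = 100L, ny = 100L, h_m = 2e-6,
                aggregate_radius_m = 4e-5, boundary_layer_m = 4e-5,
                hindrance = 0.5),
    agents = list(n_cells_per_species = 50L, seed_radius_um = 40,
                  m_seed_fmol = 1, m_div_fmol = 2, m_min_fmol = 0.1,
                  v_per_mol_m3 = 2.46e-4),
    coupling = coupling_spec(boundary_mode = boundary_mode,
                             reactor_volume = 1, n_aggregates = 1e6,
                             dt_macro = 1),
    run = list(mode = mode, seeds = as.integer(seeds))
  ), class = "aggsim_scenario")
}

# known keys per config section (unknown keys are validation errors)
.SCHEMA <- list(
  top = c("model_card", "solutes", "species", "chemostat", "grid",
          "agents", "coupling", "run"),
  model_card = c("domain", "question", "interpretation", "assumptions",
                 "formalism"),
  solutes = c("names", "diffusion_m2_per_h", "influent_uM",
              "n_content_mol_per_mol"),
  species = c("name", "mu_max_per_h", "K_NH3_uM", "K_O2_uM", "a_m_per_h",
              "yield_molX_per_molN", "formula_weight_g_per_Cmol",
              "stoich_mol_per_molN"),
  chemostat = c("HRT_h", "influent_uM", "initial_solutes_uM",
                "initial_biomass_molX_per_L", "t_end_h", "o2_mode",
                "o2_held_uM"),
  grid = c("nx", "ny", "h_m", "aggregate_radius_m", "boundary_layer_m",
           "hindrance"),
  agents = c("n_cells_per_species", "seed_radius_um", "m_seed_fmol",
             "m_div_fmol", "m_min_fmol", "v_per_mol_m3"),
  coupling = c("boundary_mode", "reactor_volume_L", "n_aggregates",
               "dt_macro_h", "representative_volume_m3"),
  run = c("mode", "seeds"))

#' Validate a scenario configuration
#'
#' Structural and physical checks: required sections and keys, positivity
#' and non-negativity invariants, species invariants (via
#' [validate_species()]), grid geometry fit, and the pseudo-steady-state
#' validity condition (diffusion relaxation time across the grid must be
#' far below the macro step). Violations carry JSON-pointer-style paths.
#'
#' @param config an `aggsim_scenario`.
#' @return character vector of violations; empty if valid.
#' @export
validate_scenario <- function(config) {
  v <- character()
  need <- c("model_card", "solutes", "species", "chemostat", "run")
  for (sec in need)
    if (is.null(config[[sec]])) v <- c(v, paste0("/", sec, ": missing"))
  if (length(v)) return(v)
  if (any(!nzchar(unlist(config$model_card))))
    v <- c(v, "/model_card: all five fields must be non-empty")
  sol <- config$solutes
  if (anyDuplicated(sol$names)) v <- c(v, "/solutes/names: duplicates")
  if (any(sol$diffusion <= 0) || any(!is.finite(sol$diffusion)))
    v <- c(v, "/solutes/diffusion_m2_per_h: must be strictly positive")
  if (any(sol$influent < 0))
    v <- c(v, "/solutes/influent_uM: must be non-negative")
  for (i in seq_along(config$species))
    v <- c(v, vapply(validate_species(config$species[[i]], sol),
                     function(m) sprintf("/species/%d: %s", i - 1, m), ""))
  cs <- config$chemostat
  if (is.null(cs$HRT) || !is.numeric(cs$HRT) || cs$HRT <= 0)
    v <- c(v, "/chemostat/HRT_h: must be a positive number")
  if (is.null(cs$t_end) || cs$t_end <= 0)
    v <- c(v, "/chemostat/t_end_h: must be > 0")
  if (any(cs$initial_solutes < 0) || any(cs$influent < 0))
    v <- c(v, "/chemostat: concentrations must be non-negative")
  if (any(cs$initial_biomass < 0))
    v <- c(v, "/chemostat/initial_biomass_molX_per_L: must be non-negative")
  if (identical(config$run$mode, "ibm")) {
    g <- config$grid; cp <- config$coupling; ag <- config$agents
    if (is.null(g) || is.null(cp) || is.null(ag)) {
      v <- c(v, "/grid|/agents|/coupling: required for ibm mode")
      return(v)
    }
    if (g$h_m <= 0) v <- c(v, "/grid/h_m: must be > 0")
    half <- (min(g$nx, g$ny) / 2 - 1) * g$h_m
    if (g$aggregate_radius_m + g$boundary_layer_m > half)
      v <- c(v, "/grid: aggregate + boundary layer exceeds the grid")
    if (ag$seed_radius_um * 1e-6 > g$aggregate_radius_m)
      v <- c(v, "/agents/seed_radius_um: seeding disc exceeds the aggregate")
    if (cp$reactor_volume <= 0)
      v <- c(v, "/coupling/reactor_volume_L: must be > 0")
    if (cp$dt_macro <= 0) v <- c(v, "/coupling/dt_macro_h: must be > 0")
    # pseudo-steady validity: diffusion relaxes much faster than one step
    L <- max(g$nx, g$ny) * g$h_m
    tau <- L^2 / (4 * min(sol$diffusion) * min(g$hindrance, 1))
    if (tau > 0.1 * cp$dt_macro)
      v <- c(v, sprintf(
        "/coupling/dt_macro_h: pseudo-steady assumption invalid (diffusion relaxation %.3g h vs step %.3g h)",
        tau, cp$dt_macro))
  }
  v
}

# plain nested list with unit-suffixed keys (the on-disk YAML schema)
as_config_list <- function(config) {
  sol <- config$solutes
  list(
    model_card = lapply(unclass(config$model_card), identity),
    solutes = list(names = as.list(sol$names),
                   diffusion_m2_per_h = as.list(sol$diffusion),
                   influent_uM = as.list(sol$influent),
                   n_content_mol_per_mol = as.list(sol$n_content)),
    species = lapply(config$species, function(s) list(
      name = s$name, mu_max_per_h = s$mu_max, K_NH3_uM = s$K_NH3,
      K_O2_uM = s$K_O2, a_m_per_h = s$a_m,
      yield_molX_per_molN = s$yield,
      formula_weight_g_per_Cmol = s$formula_weight,
      stoich_mol_per_molN = as.list(s$stoich))),
    chemostat = list(HRT_h = config$chemostat$HRT,
                     influent_uM = as.list(config$chemostat$influent),
                     initial_solutes_uM =
                       as.list(config$chemostat$initial_solutes),
                     initial_biomass_molX_per_L =
                       as.list(config$chemostat$initial_biomass),
                     t_end_h = config$chemostat$t_end,
                     o2_mode = config$chemostat$o2_mode,
                     o2_held_uM = config$chemostat$o2_value),
    grid = config$grid,
    agents = config$agents,
    coupling = list(boundary_mode = config$coupling$boundary_mode,
                    reactor_volume_L = config$coupling$reactor_volume,
                    n_aggregates = config$coupling$n_aggregates,
                    dt_macro_h = config$coupling$dt_macro),
    run = config$run)
}

from_config_list <- function(lst, where = "config") {
  unknown <- setdiff(names(lst), .SCHEMA$top)
  if (length(unknown))
    stop(where, ": unknown section(s): ", paste(unknown, collapse = ", "))
  for (sec in intersect(names(lst), names(.SCHEMA)[-1])) {
    entries <- if (sec == "species") lst[[sec]] else list(lst[[sec]])
    for (e in entries) {
      bad <- setdiff(names(e), .SCHEMA[[sec]])
      if (length(bad))
        stop("/", sec, ": unknown key(s): ", paste(bad, collapse = ", "),
             " (unit-annotated keys are required)")
    }
  }
  num <- function(x) setNames(as.numeric(unlist(x)), names(x))
  sol <- solute_set(unlist(lst$solutes$names),
                    diffusion = num(lst$solutes$diffusion_m2_per_h),
                    influent = num(lst$solutes$influent_uM),
                    n_content = if (!is.null(lst$solutes$n_content_mol_per_mol))
                      num(lst$solutes$n_content_mol_per_mol))
  species <- lapply(lst$species, function(s)
    species_params(s$name, s$mu_max_per_h, s$K_NH3_uM, s$K_O2_uM,
                   s$a_m_per_h, s$yield_molX_per_molN,
                   stoich = num(s$stoich_mol_per_molN),
                   formula_weight = s$formula_weight_g_per_Cmol))
  cs <- lst$chemostat
  chem <- chemostat_spec(cs$HRT_h, num(cs$influent_uM),
                         num(cs$initial_solutes_uM),
                         num(cs$initial_biomass_molX_per_L), cs$t_end_h,
                         o2_mode = cs$o2_mode, o2_value = cs$o2_held_uM)
  cp <- lst$coupling
  structure(list(
    model_card = do.call(model_card, lst$model_card),
    solutes = sol, species = species, chemostat = chem,
    grid = lst$grid, agents = lst$agents,
    coupling = if (!is.null(cp))
      coupling_spec(cp$boundary_mode, cp$reactor_volume_L,
                    cp$n_aggregates, cp$dt_macro_h),
    run = lst$run), class = "aggsim_scenario")
}

#' Read / write scenario configurations (YAML)
#'
#' The on-disk schema mirrors the scenario sections with unit-annotated key
#' names (`mu_max_per_h`, `HRT_h`, ...). Unknown sections or keys are
#' rejected on load; numeric values round-trip losslessly at the printed
#' precision.
#'
#' @param path YAML file path.
#' @return `load_config()`: an `aggsim_scenario`. `save_config()`: `path`,
#'   invisibly.
#' @export
load_config <- function(path) {
  lst <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("cannot parse ", path, ": ",
                                           conditionMessage(e)))
  from_config_list(lst, where = path)
}

#' @rdname load_config
#' @param config an `aggsim_scenario`.
#' @export
save_config <- function(config, path) {
  writeLines(yaml::as.yaml(as_config_list(config), precision = 15), path)
  invisible(path)
}

# md5 of the canonical YAML dump (provenance)
config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  save_config(config, f)
  unname(tools::md5sum(f))
}

#' @export
print.aggsim_scenario <- function(x, ...) {
  cat(sprintf("<aggsim_scenario> mode=%s, %d solutes, %d species\n",
              x$run$mode, length(x$solutes$names), length(x$species)))
  cat(sprintf("  HRT %g h, t_end %g h, influent NH3 %g uM, O2 %s\n",
              x$chemostat$HRT, x$chemostat$t_end,
              x$chemostat$influent[["NH3"]],
              if (x$chemostat$o2_mode == "held")
                sprintf("held at %g uM", x$chemostat$o2_value)
              else "dynamic"))
  for (s in x$species)
    cat(sprintf("  %-4s yield %.4g mol_X/mol_N\n", s$name, s$yield))
  invisible(x)
}
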