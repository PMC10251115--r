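#' Define the dissolved species tracked by a scenario
#'
#' A solute set names every dissolved compound in the model and carries its
#' aqueous diffusion coefficient, the reactor influent concentration and its
#' nitrogen content (used for nitrogen-balance audits).
#'
#' @param names character vector of unique solute identifiers. The packaged
#'   nitrification scenario uses `"NH3"`, `"O2"`, `"NO2"`, `"NO3"`.
#' @param diffusion named numeric, diffusion coefficient per solute, m^2/h.
#' @param influent named numeric, influent concentration per solute, uM.
#' @param n_content named numeric, mol N per mol solute. Defaults to 1 for
#'   NH3/NH4/NO2/NO3 and 0 otherwise.
#' @return object of class `solute_set`.
#' @examples
#' solute_set(c("NH3", "O2"),
#'            diffusion = c(NH3 = 5.5e-6, O2 = 7.2e-6),
#'            influent  = c(NH3 = 200, O2 = 100))
#' @export
solute_set <- function(names, diffusion, influent, n_content = NULL) {
  if (anyDuplicated(names)) stop("solute names must be unique")
  if (is.null(n_content)) {
    n_content <- ifelse(names %in% c("NH3", "NH4", "NO2", "NO3"), 1, 0)
    names(n_content) <- names
  }
  out <- structure(list(
    names = as.character(names),
    diffusion = diffusion[names],
    influent = influent[names],
    n_content = n_content[names]
  ), class = "solute_set")
  if (any(!is.finite(out$diffusion)) || any(out$diffusion <= 0))
    stop("diffusion coefficients must be strictly positive for every solute")
  if (any(!is.finite(out$influent)) || any(out$influent < 0))
    stop("influent concentrations must be non-negative")
  out
}

#' Define one microbial guild
#'
#' Kinetic and stoichiometric parameters for a single guild: dual-substrate
#' Monod growth on ammonia and oxygen with a specific maintenance rate, a
#' growth yield on nitrogen, and signed solute stoichiometry per mol N
#' oxidized (negative = consumed, positive = produced).
#'
#' @param name guild identifier.
#' @param mu_max maximum specific growth rate, 1/h.
#' @param K_NH3 half-saturation constant for NH3, uM.
#' @param K_O2 half-saturation constant for O2, uM.
#' @param a_m specific maintenance rate, 1/h (must be < `mu_max`).
#' @param yield growth yield Y_X/S, mol biomass C per mol N oxidized.
#' @param stoich named numeric, mol solute per mol N oxidized; must contain an
#'   entry for every solute of the scenario's [solute_set()].
#' @param formula_weight biomass formula weight, g per C-mol (default 24.6
#'   for CH1.8O0.5N0.2); used only to convert to weight fractions.
#' @return object of class `species_params`.
#' @examples
#' species_params("AO", mu_max = 0.01, K_NH3 = 1, K_O2 = 3.13, a_m = 0.001,
#'                yield = 4.09e-2, stoich = c(NH3 = -1, O2 = -1.5, NO2 = 1))
#' @export
species_params <- function(name, mu_max, K_NH3, K_O2, a_m, yield, stoich,
                           formula_weight = 24.6) {
  structure(list(name = name, mu_max = mu_max, K_NH3 = K_NH3, K_O2 = K_O2,
                 a_m = a_m, yield = yield, stoich = stoich,
                 formula_weight = formula_weight),
            class = "species_params")
}

#' Model card: declarative description of a scenario
#'
#' Free-text record of the five components that constitute a model of a
#' natural system -- the domain studied, the scientific question, the
#' interpretation (scales resolved), the assumptions, and the mathematical
#' formalism. Attached to every packaged scenario as provenance.
#'
#' @param domain,question,interpretation,assumptions,formalism character
#'   descriptors; all must be non-empty.
#' @return object of class `model_card`.
#' @export
model_card <- function(domain, question, interpretation, assumptions,
                       formalism) {
  fields <- list(domain = domain, question = question,
                 interpretation = interpretation, assumptions = assumptions,
                 formalism = formalism)
  if (any(!nzchar(unlist(fields))))
    stop("all five model card fields must be non-empty")
  structure(fields, class = "model_card")
}

#' Specific growth rate under dual-substrate Monod kinetics with maintenance
#'
#' mu = mu_max * NH3/(K_NH3 + NH3) * O2/(K_O2 + O2) - a_m. The result lies in
#' `[-a_m, mu_max - a_m)` and is strictly increasing in each substrate.
#' Vectorized over concentrations.
#'
#' @param sp a [species_params()] object.
#' @param c_nh3 ammonia concentration, uM (>= 0).
#' @param c_o2 oxygen concentration, uM (>= 0).
#' @return specific growth rate, 1/h.
#' @examples
#' ao <- species_params("AO", 0.01, 1, 3.13, 0.001, 4.09e-2,
#'                      c(NH3 = -1, O2 = -1.5))
#' monod_growth_rate(ao, 0, 0)        # -a_m: pure maintenance decay
#' monod_growth_rate(ao, 1, 3.13)     # half-saturation on both: 0.0015
#' @export
monod_growth_rate <- function(sp, c_nh3, c_o2) {
  if (any(c_nh3 < 0) || any(c_o2 < 0))
    stop("concentrations must be non-negative")
  sp$mu_max * c_nh3 / (sp$K_NH3 + c_nh3) * c_o2 / (sp$K_O2 + c_o2) - sp$a_m
}

#' Volumetric solute turnover rates of one guild
#'
#' Nitrogen oxidation proceeds at `(1/yield) * max(mu, 0) * X`; each solute's
#' rate is that flux scaled by the guild's signed stoichiometry. Growth-rate
#' deficits below zero (maintenance exceeding supply) consume biomass, not
#' external substrate, so uptake is clamped at mu <= 0.
#'
#' @param sp a [species_params()] object.
#' @param biomass_X guild biomass, mol_X / L (>= 0).
#' @param conc named per-solute concentrations, uM; must contain `NH3` and
#'   `O2` and every solute named in `sp$stoich`.
#' @return named per-solute volumetric rates, uM/h (negative = consumed).
#' @export
solute_rates <- function(sp, biomass_X, conc) {
  if (biomass_X < 0) stop("biomass must be non-negative")
  if (!all(names(sp$stoich) %in% names(conc)))
    stop("stoichiometry names an unknown solute: ",
         paste(setdiff(names(sp$stoich), names(conc)), collapse = ", "))
  mu <- monod_growth_rate(sp, conc[["NH3"]], conc[["O2"]])
  r_n <- (1 / sp$yield) * max(mu, 0) * biomass_X * .MOLX_TO_UM  # uM N / h
  rates <- setNames(numeric(length(conc)), names(conc))
  rates[names(sp$stoich)] <- sp$stoich * r_n
  rates
}

#' Check a guild definition against its invariants
#'
#' Reports (rather than throws) violations: non-positive rates or constants,
#' maintenance not below mu_max, non-positive yield, stoichiometry missing a
#' solute of the scenario's solute set.
#'
#' @param sp a [species_params()] object.
#' @param solutes optional [solute_set()]; if given, stoichiometry coverage
#'   is checked against it.
#' @return character vector of violations; empty if all invariants hold.
#' @export
validate_species <- function(sp, solutes = NULL) {
  v <- character()
  if (!is.numeric(sp$mu_max) || sp$mu_max <= 0)
    v <- c(v, "mu_max must be > 0")
  if (!is.numeric(sp$K_NH3) || sp$K_NH3 <= 0)
    v <- c(v, "K_NH3 must be > 0")
  if (!is.numeric(sp$K_O2) || sp$K_O2 <= 0)
    v <- c(v, "K_O2 must be > 0")
  if (!is.numeric(sp$a_m) || sp$a_m < 0 ||
      (is.numeric(sp$mu_max) && sp$mu_max > 0 && sp$a_m >= sp$mu_max))
    v <- c(v, "a_m must satisfy 0 <= a_m < mu_max")
  if (!is.numeric(sp$yield) || sp$yield <= 0)
    v <- c(v, "yield must be > 0")
  if (!is.null(solutes)) {
    missing <- setdiff(solutes$names, names(sp$stoich))
    if (length(missing))
      v <- c(v, paste0("stoich missing entry for solute(s): ",
                       paste(missing, collapse = ", ")))
  }
  v
}

#' @export
print.species_params <- function(x, ...) {
  cat(sprintf("<species_params> %s\n", x$name))
  cat(sprintf("  mu_max %.4g /h, K_NH3 %.4g uM, K_O2 %.4g uM, a_m %.4g /h\n",
              x$mu_max, x$K_NH3, x$K_O2, x$a_m))
  cat(sprintf("  yield %.4g mol_X/mol_N, formula weight %.4g g/C-mol\n",
              x$yield, x$formula_weight))
  cat("  stoich:", paste(sprintf("%s %+g", names(x$stoich), x$stoich),
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.model_card <- function(x, ...) {
  cat("<model card>\n")
  for (f in names(x)) cat(sprintf("  %-14s %s\n", f, x[[f]]))
  invisible(x)
}
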