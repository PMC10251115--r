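#' Specify chemostat (CSTR) operation
#'
#' @param HRT hydraulic retention time, h (> 0). The dilution rate is 1/HRT.
#' @param influent named per-solute influent concentrations, uM.
#' @param initial_solutes named per-solute initial reactor concentrations, uM.
#' @param initial_biomass named per-guild initial biomass, mol_X / L.
#' @param t_end simulated time, h (> 0).
#' @param o2_mode `"dynamic"` integrates the O2 balance like any solute;
#'   `"held"` pins bulk O2 at `o2_value` (aeration control), its derivative 0.
#' @param o2_value held bulk O2 concentration, uM (used when `o2_mode` is
#'   `"held"`; defaults to the O2 entry of `initial_solutes`).
#' @return object of class `chemostat_spec`.
#' @export
chemostat_spec <- function(HRT, influent, initial_solutes, initial_biomass,
                           t_end, o2_mode = c("dynamic", "held"),
                           o2_value = NULL) {
  o2_mode <- match.arg(o2_mode)
  if (!is.numeric(HRT) || HRT <= 0) stop("HRT must be > 0")
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be > 0")
  if (any(influent < 0) || any(initial_solutes < 0))
    stop("concentrations must be non-negative")
  if (any(initial_biomass < 0)) stop("initial biomass must be non-negative")
  if (is.null(o2_value)) o2_value <- initial_solutes[["O2"]]
  structure(list(HRT = HRT, influent = influent,
                 initial_solutes = initial_solutes,
                 initial_biomass = initial_biomass, t_end = t_end,
                 o2_mode = o2_mode, o2_value = o2_value),
            class = "chemostat_spec")
}

#' Right-hand side of the well-mixed chemostat ODE system
#'
#' Solutes follow the CSTR mass balance
#' `d[S]/dt = (1/HRT) ([S]_influent - [S]) + R_BL` with the reaction term
#' summed over guilds (`R_BL = sum_i stoich * (1/Y_i) mu_i^+ X_i`), and each
#' guild's biomass follows `dX/dt = (mu - 1/HRT) X`. With `o2_mode = "held"`
#' the O2 derivative is 0.
#'
#' @param state named state vector: solute concentrations (uM) followed by
#'   per-guild biomass (mol_X/L), in the order of `spec$influent` and
#'   `species`.
#' @param spec a [chemostat_spec()].
#' @param species list of [species_params()].
#' @return named derivative vector in the same order as `state`.
#' @export
chemostat_rhs <- function(state, spec, species) {
  sol_names <- names(spec$influent)
  sp_names <- vapply(species, `[[`, "", "name")
  if (length(state) != length(sol_names) + length(species))
    stop("state length does not match spec solutes + species")
  s <- pmax(state[seq_along(sol_names)], 0)
  names(s) <- sol_names
  X <- pmax(state[length(sol_names) + seq_along(species)], 0)
  ds <- (spec$influent - s) / spec$HRT
  dX <- numeric(length(species))
  for (i in seq_along(species)) {
    sp <- species[[i]]
    mu <- monod_growth_rate(sp, s[["NH3"]], s[["O2"]])
    ds <- ds + solute_rates(sp, X[i], s)
    dX[i] <- (mu - 1 / spec$HRT) * X[i]
  }
  if (spec$o2_mode == "held") ds[["O2"]] <- 0
  setNames(c(ds, dX), c(sol_names, sp_names))
}

#' Integrate the chemostat model (Model 1) to its final time
#'
#' Stiff-safe adaptive integration (`deSolve::lsoda`) of [chemostat_rhs()]
#' over `[0, t_end]`, with an auxiliary quadrature of the net dilution
#' exchange of nitrogen so the nitrogen balance can be audited exactly.
#' Negative excursions below `atol` are truncated at 0 in the output.
#'
#' @param spec a [chemostat_spec()].
#' @param species list of [species_params()].
#' @param solutes optional [solute_set()] (nitrogen content per solute for
#'   the balance audit; defaults to name-based assignment).
#' @param rtol,atol integrator tolerances.
#' @param n_out number of regularly spaced output times.
#' @return an `aggsim_result` with the solute/biomass [trajectory], final
#'   weight fractions, detected steady-state time and the relative
#'   nitrogen-balance closure error.
#' @seealso [detect_steady_state()], [weight_fractions()]
#' @export
simulate_chemostat <- function(spec, species, solutes = NULL, rtol = 1e-8,
                               atol = 1e-12, n_out = 600) {
  sol_names <- names(spec$influent)
  sp_names <- vapply(species, `[[`, "", "name")
  n_content <- if (is.null(solutes))
    setNames(ifelse(sol_names %in% c("NH3", "NH4", "NO2", "NO3"), 1, 0),
             sol_names)
  else solutes$n_content[sol_names]
  y0 <- c(spec$initial_solutes[sol_names],
          setNames(spec$initial_biomass[sp_names], sp_names),
          qN = 0)
  ns <- length(sol_names)
  deriv <- function(t, y, parms) {
    d <- chemostat_rhs(y[seq_len(ns + length(species))], spec, species)
    # net dilution exchange of dissolved N (influent minus effluent flux)
    s <- pmax(y[seq_len(ns)], 0)
    dqN <- sum(n_content * (spec$influent - s)) / spec$HRT
    list(c(d, dqN))
  }
  times <- seq(0, spec$t_end, length.out = n_out)
  out <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("chemostat integration failed; last state: ",
         paste(sprintf("%s=%.3g", colnames(out)[-1], out[nrow(out), -1]),
               collapse = ", "))
  m <- as.matrix(out[, -1, drop = FALSE])
  m[m < 0 & m > -atol] <- 0
  m[m < 0] <- 0   # clip any residual negative excursion
  traj <- structure(list(times = out[, 1],
                         solutes = m[, sol_names, drop = FALSE],
                         biomass = m[, sp_names, drop = FALSE]),
                    class = "aggsim_trajectory")
  # nitrogen closure: change in dissolved N must equal net dilution exchange
  # (stoichiometry conserves N: oxidation converts NH3 into NO2/NO3 1:1)
  tn <- m[, sol_names, drop = FALSE] %*% n_content
  n_in_scale <- sum(n_content * spec$influent) * spec$t_end / spec$HRT +
    tn[1] + atol
  n_err <- abs((tn[length(tn)] - tn[1]) - m[nrow(m), "qN"]) / n_in_scale
  fw <- vapply(species, `[[`, 0, "formula_weight")
  final_bio <- setNames(m[nrow(m), sp_names], sp_names)
  structure(list(model = "chemostat",
                 trajectory = traj,
                 species = sp_names,
                 weight_fractions = weight_fractions(final_bio, fw),
                 final_biomass = final_bio,
                 final_solutes = setNames(m[nrow(m), sol_names], sol_names),
                 steady_state_time = if (spec$t_end >= 2 * 2400)
                   detect_steady_state(traj) else NA_real_,
                 n_balance_rel_error = as.numeric(n_err),
                 provenance = list(package_version =
                                     as.character(utils::packageVersion("aggsim")))),
            class = "aggsim_result")
}

#' Detect the time a trajectory reaches steady state
#'
#' Earliest output time after which, over a trailing window, the relative
#' change of every state variable stays below `rel_tol` (relative to the
#' window maximum magnitude, floored at `abs_floor` so that states decayed
#' to numerical zero count as steady).
#'
#' @param traj an `aggsim_trajectory` (from [simulate_chemostat()] or
#'   [run_multiscale()]).
#' @param rel_tol relative-change tolerance (default 1e-6).
#' @param window window length, h (default 2400, i.e. 100 d).
#' @param abs_floor magnitude floor for the relative change (default 1e-9).
#' @return steady-state time (h), or `NA_real_` if not reached.
#' @export
detect_steady_state <- function(traj, rel_tol = 1e-6, window = 2400,
                                abs_floor = 1e-9) {
  times <- traj$times
  if (max(times) - min(times) < window)
    stop("trajectory must span at least one window")
  M <- cbind(traj$solutes, traj$biomass)
  for (i in seq_along(times)) {
    j <- which(times >= times[i] & times <= times[i] + window)
    if (times[length(times)] - times[i] < window) break
    sub <- M[j, , drop = FALSE]
    hi <- apply(sub, 2, max); lo <- apply(sub, 2, min)
    rel <- (hi - lo) / pmax(pmax(abs(hi), abs(lo)), abs_floor)
    if (all(rel < rel_tol)) return(times[i])
  }
  NA_real_
}

#' Biomass weight fractions
#'
#' Converts per-guild molar biomass to percent of total biomass by weight,
#' using each guild's formula weight: `100 * m_i X_i / sum_j m_j X_j`.
#'
#' @param biomass named per-guild biomass (mol_X/L, or any amount
#'   proportional to it).
#' @param formula_weight per-guild formula weight, g per C-mol; recycled
#'   (default 24.6 for all guilds).
#' @return named weight fractions in percent, summing to 100.
#' @examples
#' weight_fractions(c(AO = 0.14, CMX = 0.86))  # 14 / 86 wt%
#' @export
weight_fractions <- function(biomass, formula_weight = 24.6) {
  if (all(biomass <= 0))
    stop("weight fractions undefined: total biomass is zero")
  mass <- biomass * rep_len(formula_weight, length(biomass))
  100 * mass / sum(mass)
}
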