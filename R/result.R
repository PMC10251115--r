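#' @export
print.aggsim_trajectory <- function(x, ...) {
  cat(sprintf("<aggsim_trajectory> %d time points over %g h\n",
              length(x$times), max(x$times)))
  cat("  solutes:", paste(colnames(x$solutes), collapse = ", "), "\n")
  cat("  species:", paste(colnames(x$biomass), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.aggsim_result <- function(x, ...) {
  cat(sprintf("<aggsim_result> %s, %g h simulated\n", x$model,
              max(x$trajectory$times)))
  wf <- x$weight_fractions
  cat("  weight fractions:",
      paste(sprintf("%s %.1f wt%%", names(wf), wf), collapse = ", "), "\n")
  cat(sprintf("  steady state: %s\n",
              if (is.na(x$steady_state_time)) "not reached"
              else sprintf("from %g h", x$steady_state_time)))
  if (!is.null(x$n_balance_rel_error) && !is.na(x$n_balance_rel_error))
    cat(sprintf("  N-balance closure: %.2g relative\n",
                x$n_balance_rel_error))
  invisible(x)
}

#' Summarize a simulation run (or replicate set)
#'
#' Collects the quantities reported for a run: final biomass weight
#' fractions, steady-state time, residual bulk concentrations,
#' nitrogen-balance closure, and (for replicate sets) the mean and standard
#' deviation of the weight fractions over seeds.
#'
#' @param result an `aggsim_result`, or the list returned by
#'   [replicate_runs()].
#' @return a list of class `aggsim_summary`.
#' @export
summarize <- function(result) {
  if (!is.null(result$runs)) {   # replicate set
    per_run <- lapply(result$runs, summarize)
    out <- list(kind = "replicates",
                n = length(result$runs),
                weight_fractions = result$weight_fractions,
                mean_weight_fractions = result$mean,
                sd_weight_fractions = result$sd,
                runs = per_run)
    return(structure(out, class = "aggsim_summary"))
  }
  structure(list(
    kind = result$model,
    weight_fractions = result$weight_fractions,
    steady_state_time_h = result$steady_state_time,
    final_solutes_uM = result$final_solutes,
    n_balance_rel_error = result$n_balance_rel_error,
    seed = result$provenance$seed,
    config_hash = result$provenance$config_hash,
    package_version = result$provenance$package_version
  ), class = "aggsim_summary")
}

#' @export
print.aggsim_summary <- function(x, ...) {
  if (identical(x$kind, "replicates")) {
    cat(sprintf("<aggsim_summary> %d replicates\n", x$n))
    m <- x$mean_weight_fractions; s <- x$sd_weight_fractions
    cat("  weight fractions:",
        paste(sprintf("%s %.1f +/- %.1f wt%%", names(m), m, s),
              collapse = ", "), "\n")
  } else {
    cat(sprintf("<aggsim_summary> %s\n", x$kind))
    wf <- x$weight_fractions
    cat("  weight fractions:",
        paste(sprintf("%s %.1f wt%%", names(wf), wf), collapse = ", "), "\n")
    if (!is.null(x$final_solutes_uM))
      cat("  residual solutes (uM):",
          paste(sprintf("%s %.3g", names(x$final_solutes_uM),
                        x$final_solutes_uM), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.aggsim_result <- function(object, ...) summarize(object)

#' Time-series plot of a simulation run
#'
#' Two panels: bulk solute concentrations and per-guild biomass weight
#' fraction over time.
#'
#' @param x an `aggsim_result`.
#' @param ... unused.
#' @export
plot.aggsim_result <- function(x, ...) {
  tr <- x$trajectory
  t_d <- tr$times / 24
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::matplot(t_d, tr$solutes, type = "l", lty = 1,
                    xlab = "time (d)", ylab = "bulk concentration (uM)")
  graphics::legend("right", colnames(tr$solutes), lty = 1,
                   col = seq_len(ncol(tr$solutes)), bty = "n")
  tot <- rowSums(tr$biomass)
  frac <- 100 * tr$biomass / ifelse(tot > 0, tot, NA)
  graphics::matplot(t_d, frac, type = "l", lty = 1, ylim = c(0, 100),
                    xlab = "time (d)", ylab = "biomass fraction (wt%)")
  graphics::abline(h = 50, lty = 3, col = "grey")
  graphics::legend("right", colnames(tr$biomass), lty = 1,
                   col = seq_len(ncol(tr$biomass)), bty = "n")
  invisible(x)
}

#' Write a run's time series as tidy long-format CSV
#'
#' Columns `time_h`, `variable`, `value`; solutes in uM, biomass in
#' mol_X/L.
#'
#' @param result an `aggsim_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(result, path) {
  tr <- result$trajectory
  wide <- cbind(tr$solutes, tr$biomass)
  long <- data.frame(
    time_h = rep(tr$times, ncol(wide)),
    variable = rep(colnames(wide), each = length(tr$times)),
    value = as.vector(wide))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
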