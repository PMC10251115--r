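# aggsim

Multiscale simulation of microbial aggregates in chemostat culture, built
around one question from nitrification ecology: can a **complete ammonia
oxidizer** (comammox, NH3 → NO3⁻) outcompete a **canonical ammonia
oxidizer** (NH3 → NO2⁻) under ammonia limitation, when the two differ *only*
in growth yield?

The package implements the same community at two levels of description:

* **Model 1 — well-mixed chemostat (ODE).** Coupled CSTR mass balances
  `d[S]/dt = (1/HRT)([S]in − [S]) + R_BL` and biomass balances
  `dX/dt = (μ − 1/HRT)X`, with dual-Monod growth and maintenance
  `μ = μmax · [NH3]/(K_NH3+[NH3]) · [O2]/(K_O2+[O2]) − a_m`,
  integrated to steady state (deSolve).
* **Model 2 — individual-based aggregate model (IbM).** Discrete cells in a
  2-D aggregate + diffusive boundary layer; each growth step solves the
  pseudo-steady reaction–diffusion problem `0 = ∇·(D∇[S]) + R_xy` for the
  local fields (compiled SOR solver), grows/divides/culls/shoves the cells,
  and couples back to the bulk liquid by representative-volume scale-up
  (`R_BL = Σ R_xy·h³ · n_agg / V`), with fixed or dynamic boundary
  conditions.

Both guilds share identical kinetics (μmax = 0.01 h⁻¹, K_NH3 = 1.0 µM,
K_O2 = 3.13 µM, a_m = 0.001 h⁻¹) and differ only in yield
(4.09×10⁻² vs 6.51×10⁻² mol_X/mol_N). Well mixed, that difference is
neutral — the biomass ratio is conserved, a 50/50 inoculum stays 50/50.
With diffusion gradients resolved, growth becomes transport-limited and the
higher-yield comammox guild compounds faster and takes over; make diffusion
arbitrarily fast and the coupled model collapses back onto the ODE and the
enrichment vanishes. The methods vignette
(`vignettes/multiscale-nitrification.Rmd`) documents the model equations,
parameter defaults and numerical choices.

## Worked example

```r
library(aggsim)

sc  <- comammox_scenario()                     # packaged two-guild scenario
res <- simulate_chemostat(sc$chemostat, sc$species, sc$solutes)
res
#> <aggsim_result> chemostat, 43800 h simulated
#>   weight fractions: AO 50.0 wt%, CMX 50.0 wt%
#>   steady state: from 2413.02 h
#>   N-balance closure: 7.7e-19 relative
round(res$final_solutes, 2)
#>    NH3     O2    NO2    NO3
#>   1.14 100.00 122.13  76.73
```

The well-mixed reactor reaches steady state after ~100 d with residual
ammonia of 1.14 µM (ammonia-limited, near K_NH3) and the 50/50 inoculum
unchanged — with identical kinetics the yield difference shows up only in
the product split (more NO2⁻ than NO3⁻, because the lower-yield guild
oxidizes more N per unit biomass), never in the community composition.

The coupled individual-based run uses the same scenario in `ibm` mode:

```r
sc2 <- comammox_scenario(mode = "ibm", t_end_d = 300)
rep <- replicate_runs(sc2, seeds = 1:3)   # ~10 min
rep$mean                                  # comammox enriched well above 50 wt%
```

A thin command-line interface wraps the same functions
(`make-scenario`, `validate`, `run-ode`, `run-ibm`, `summarize`):

```sh
Rscript $(Rscript -e 'cat(system.file("cli","aggsim.R",package="aggsim"))') \
    make-scenario comammox --out scenario.yaml
Rscript .../aggsim.R run-ode --config scenario.yaml --out run1/
```

Scenario files are YAML with unit-annotated keys; runs emit tidy
`timeseries.csv` and a `summary.json` carrying weight fractions, residual
concentrations, nitrogen-balance closure, config hash and seed.

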