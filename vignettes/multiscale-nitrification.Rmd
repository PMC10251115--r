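---
title: "Two models of one nitrifying community: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two models of one nitrifying community: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggsim)
```

`aggsim` simulates the competition between a complete ammonia oxidizer
(comammox, NH3 &rarr; NO3^-^) and a canonical ammonia oxidizer
(NH3 &rarr; NO2^-^) in continuous culture, at two levels of description that
share every biological parameter:

* **Model 1** — a well-mixed chemostat (CSTR) integrated as an ODE system;
* **Model 2** — an individual-based model (IbM) of a microbial aggregate,
  where discrete cells experience the solute field of a 2-D
  reaction–diffusion micro-scale and feed back on the reactor's bulk liquid
  through a multiscale coupler.

The scientific point of the pair is a *mechanism contrast*. The two guilds
share identical Monod kinetics and maintenance — no kinetic competition —
and differ only in growth yield. In a well-mixed reactor that difference is
neutral: both guilds' per-capita growth depends only on the shared bulk
concentrations, so their biomass ratio is a conserved quantity and a 50/50
inoculum stays 50/50 forever. Once diffusion gradients exist, growth becomes
supply-limited rather than concentration-limited: a patch of biomass can
only grow as fast as substrate diffuses into it, and the biomass it builds
per mole of nitrogen captured is proportional to its yield. The
higher-yield comammox guild therefore compounds faster wherever transport,
not kinetics, is limiting — and the enrichment disappears again when
diffusion is made arbitrarily fast. This vignette records the model
equations, the parameter choices, and the numerical design decisions.

## Growth model

Both models use dual-substrate Monod kinetics with a maintenance term:

$$\mu = \mu_\max \frac{[\mathrm{NH_3}]}{K_{\mathrm{NH_3}} + [\mathrm{NH_3}]}
              \frac{[\mathrm{O_2}]}{K_{\mathrm{O_2}} + [\mathrm{O_2}]} - a_m$$

so $\mu \in [-a_m,\ \mu_\max - a_m)$: starved biomass decays at the
maintenance rate. Nitrogen oxidation is tied to growth through the yield,
$r_N = \mu^+ X / Y_{X/S}$, with $\mu^+ = \max(\mu, 0)$.

**Uptake clamping.** A literal reading of the reaction term
$R = (1/Y)\,\mu\,X$ would make starving biomass ($\mu < 0$) *release*
substrate. We clamp substrate exchange at $\mu \le 0$: maintenance consumes
biomass, not external substrate, while the full (possibly negative) $\mu$
still drives biomass dynamics. This is a deliberate deviation from the bare
formula, chosen for mass-balance sanity; under the packaged scenario it only
matters for cells deep inside the aggregate where $\mu < 0$.

**Stoichiometry.** Nitrogen oxidation products are tracked explicitly
(AO: NH3 &rarr; NO2^-^; CMX: NH3 &rarr; NO3^-^, 1:1 in N), which makes the
nitrogen balance a real audit: total dissolved N is conserved by the
reaction rows, so any closure error is numerical. O2 stoichiometry is not
part of the published parameter set; we default to the standard catabolic
values 1.5 mol O2/mol N for ammonia oxidation to nitrite and 2.0 for
complete oxidation to nitrate (configurable). Because the packaged scenario
holds O2 non-limiting, results are insensitive to this choice. Nitrogen
assimilation into biomass is neglected in the solute balances (the reaction
term uses only the catabolic $1/Y$); this too is configurable in principle
but off by default.

**Biomass units.** Biomass is measured in C-mol ("mol_X"), converted to
grams only for weight fractions using a formula weight of 24.6 g/C-mol
(CH~1.8~O~0.5~N~0.2~). Cells carry femtomoles; the default seed cell of
1 fmol_X corresponds to a typical bacterial carbon content.

## Model 1: the chemostat

$$\frac{d[S]}{dt} = \frac{1}{\mathrm{HRT}}([S]_\mathrm{in} - [S]) + R_{BL},
\qquad \frac{dX_i}{dt} = (\mu_i - 1/\mathrm{HRT})\,X_i$$

The packaged scenario fixes $\mu_\max = 0.01\,h^{-1}$,
$K_{\mathrm{NH_3}} = 1.0\,\mu M$, $K_{\mathrm{O_2}} = 3.13\,\mu M$,
$a_m = 0.001\,h^{-1}$ for both guilds and yields of
$4.09\times10^{-2}$ (AO) and $6.51\times10^{-2}$ (CMX) mol_X/mol_N, run to
steady state over 1825 d. Two operating parameters are not part of the
published set and are package choices:

* **HRT = 240 h** (dilution rate 0.0042 h^-1^), safely below the washout
  bound $\mu_\max f_{O_2} - a_m \approx 0.0087$ h^-1^;
* **influent NH3 = 200 µM**, which leaves the steady-state reactor
  ammonia-limited (residual NH3 ≈ 1.1 µM, close to $K_{\mathrm{NH_3}}$);
* **bulk O2 held at 100 µM** (non-limiting vs $K_{\mathrm{O_2}}$), the
  `o2_mode = "held"` aeration idealization; a dynamic O2 balance is
  available.

Integration uses `deSolve::lsoda` (stiff-safe, adaptive) at
`rtol = 1e-8`, `atol = 1e-12`, with an auxiliary quadrature of the net
dilution exchange of nitrogen so that the closure
$\Delta N_\mathrm{bulk} = N_\mathrm{in} - N_\mathrm{out}$ can be verified;
it holds to ~1e-18 relative, and the packaged tests require < 1e-6.
Steady state is detected as the earliest time after which no state changes
by more than 1e-6 (relative) over a 100-d window.

Because the guilds' kinetics are identical, $X_1/X_2$ is conserved exactly
(the yield enters substrate drawdown, not relative growth), so the 50/50
outcome of Model 1 is an analytic consequence as well as a simulation
result. This neutrality is tested as an invariant for arbitrary initial
ratios.

## Model 2: micro-scale

The aggregate lives on a 2-D voxel grid (default 100×100 voxels of
$h = 2\,\mu m$; the grid is planar with unit depth $h$, so a voxel
represents $h^3$). A circular aggregate (default radius 40 µm) sits at the
centre, wrapped in a diffusive boundary layer (default thickness 40 µm);
every voxel beyond the boundary layer is held at the bulk concentration
(Dirichlet), representing the well-mixed liquid. Within one growth step the
solute fields are treated as at *pseudo-steady state*:

$$0 = \nabla\!\cdot\!(D \nabla [S]) + R_{xy}$$

justified by the scale gap between diffusive relaxation across the grid
(~10^-3^ h) and the 1 h growth step; the configuration validator asserts
this gap. Diffusion coefficients are not part of the published set; we use
literature-typical aqueous values ($D_{\mathrm{NH_3}} = 5.5\times10^{-6}$,
$D_{\mathrm{O_2}} = 7.2\times10^{-6}$ m²/h), halved inside aggregate voxels
(biofilm hindrance factor 0.5, configurable).

The discrete operator is the standard 5-point stencil in flux form with
harmonic-mean face conductances (exact for uniform $D$); bulk-edge voxels
are Dirichlet values and array edges without neighbours are no-flux. The
linear fixed-rate problem is solved by projected SOR (ω = 1.9 by default)
to a residual below $10^{-6} \max |R|$; concentrations are kept
non-negative, and voxels pinned at zero (demand exceeding diffusive supply)
are counted and reported. Verification problems with closed forms — the
1-D slab with a constant sink, the pure-diffusion limit, a brute-force
explicit-time-stepping oracle — are part of the test suite.

The Monod reaction makes the coupled problem nonlinear. Two equivalent
treatments are implemented: a classical damped Picard iteration (rates
frozen per linear solve, concentration updates damped by 0.5, at most 200
outer iterations) and a *fused* relaxation that re-evaluates the local
uptake inside every SOR sweep, linearized per voxel as
$\kappa = U(c)/\max(c, 10^{-2})$ so iterates stay non-negative. Both
converge to the same fixed point (tested); the fused path is the default
because it converges in one pass and is far cheaper on the warm restarts
of the coupled loop. Within the coupled run the per-step relaxation
tolerance is 1e-5 (relative to the largest local uptake); stand-alone
solves default to 1e-6. Fields are warm-started each macro step by linear
extrapolation from the previous two steps.

## Model 2: individuals

Cells are discs (radius from mass via a biomass specific volume of
2.46×10^-4^ m³/mol_X, i.e. 24.6 g/C-mol at 100 g/L dry density) with
continuous positions, read their local concentrations from the voxel that
contains their centre (piecewise-constant; boundary positions belong to the
higher voxel), and grow exponentially at their local $\mu$ over the 1 h
agent step — the step length matches the characteristic division time.
Division and death rules are not constrained by the published scenario;
the package defaults are:

* divide at $m \ge m_\mathrm{div} = 2\,m_\mathrm{seed}$ into two equal
  halves, the daughter placed at contact distance in a uniformly random
  direction (mass conserved exactly);
* cull below $m_\mathrm{min} = 0.1\,m_\mathrm{seed}$, with removed mass
  kept in a per-guild ledger so biomass bookkeeping is auditable;
* resolve overlaps by pairwise shoving (half the overlap each, id order,
  spatial hashing) until the worst overlap is below 1% of the mean radius.

The aggregate voxel mask follows the cells: any occupied voxel counts as
aggregate for reaction bookkeeping and diffusive hindrance, so colony
expansion is agent-driven rather than a continuum moving boundary.

The initial condition is the dominant unquantified driver of the exact
final split: the packaged fixture seeds 50 cells per guild uniformly in a
40 µm disc. All of its parameters are configuration knobs.

## The multiscale coupler

Each macro step (1 h): (1) co-converge cell uptake and solute fields;
(2) grow/divide/cull/shove; (3) scale the converged rates up to the
reactor, $R_{BL} = \sum_{xy} R_{xy} h^3 \cdot
n_\mathrm{agg} / V_\mathrm{reactor}$ (the simulated aggregate is a
statistically representative volume); (4) advance the bulk by the exact
exponential update of the linear CSTR balance with $R_{BL}$ frozen over
the step. Product (NO2^-^/NO3^-^) fields are not solved at the micro-scale
— they do not feed back on kinetics — and their release is scaled up
stoichiometrically from the nitrogen oxidized.

Boundary modes follow the scale-down options: `"dynamic"` (default,
bidirectional — the bulk responds to the aggregate and vice versa) and
`"fixed"` (unidirectional, bulk prescribed; used for controlled
experiments such as the single-cell exponential-growth check).

**Biomass washout.** In dynamic mode every cell is removed with probability
$1 - e^{-\Delta t/\mathrm{HRT}}$ per step. The simulated aggregate
represents suspended aggregates that leave with the effluent; without this
term the IbM has no steady state and cannot agree with Model 1 in the
fast-diffusion limit, where the coupled model must reduce to the chemostat
ODE (this reduction is an acceptance test). Removal is unbiased between
guilds, so it does not contribute to selection — but it does add neutral
drift of order $\sqrt{\smash[b]{\int p\,dt/N}}$ to the composition, which
is why deterministic-limit checks use populations of 10^4^ cells rather
than the fixture's 100.

**Scale-up factor.** One simulated aggregate represents
$n_\mathrm{agg} = 10^6$ aggregates in a 1 L reactor — an aggregate density
typical of an enrichment culture, and the main free scaling knob. With the
packaged kinetics this puts the steady-state aggregate at a few thousand
cells, large enough for composition drift to be modest and small enough to
simulate years of culture in minutes.

**Replicates.** The deterministic ODE is run once; IbM results are
reported as mean ± SD over three RNG seeds (1, 2, 3 by default). A fixed
seed reproduces a run bit-for-bit; this is a tested contract.

## Nitrogen accounting

Every exchange path is bookkept independently: cumulative influent,
cumulative effluent (exact integrals of the exponential updates), net
reaction exchange with the aggregate (zero-sum in N by stoichiometry), and
the bulk inventory. The coupled model's closure is required to hold to
better than 1e-3 (it holds to ~1e-16 in practice because the update is
exact); the ODE closure to 1e-6. Culled and washed-out biomass are tracked
in per-guild ledgers (they carry no N in the default no-assimilation
configuration).

## Problem sizes used in the packaged checks

The packaged acceptance checks run: Model 1 at the full 1825 d horizon
(seconds); the reduced Model 2 fixture — the default 100×100 grid, 40 µm
aggregate — for 300 d at the first replicate seed; the fast-diffusion
contrast at $D \times 10^6$ for 60 d with 6×10^3^ cells/guild seeded (one
aggregate per 5 µL, so neutral drift is far below the 2 wt% bound); and a
down-scaled 60×60 / 20 µm configuration (influent 50 µM NH3, one aggregate
per µL) for the direction-of-effect scan over diffusion scales 1×/10×/100×
at 3 seeds each. These sizes were chosen so the full suite runs on a laptop
in well under half an hour while leaving the qualitative outcomes far from
their decision thresholds.

## What the generator does and does not emulate

The scenario generator produces the idealized study conditions: ideal CSTR
hydraulics, a single representative aggregate, constant influent, held O2,
two guilds differing only in yield. It does not emulate features of real
enrichment cultures such as heterotrophic satellites, EPS or inert biomass,
pH/temperature dependence of kinetics, acid–base speciation, aggregate
breakage, or multiple interacting aggregates. Passing tests therefore
demonstrate the internal consistency of the two-model contrast — neutrality
when well mixed, yield-driven enrichment under diffusion limitation, and
the collapse of that enrichment when transport is fast — not a quantitative
prediction for any particular reactor. The exact enriched fraction depends
on unpublished details of the individual-based configuration (grid,
geometry, seeding, boundary mode); the packaged fixture documents one
defensible choice and exposes every knob.

## Known limitations

* 2-D planar geometry with unit depth; no radial/cylindrical correction.
* Piecewise-constant cell-to-voxel mapping (no interpolation), consistent
  with voxel-level reaction bookkeeping but first-order accurate in space.
* The fused micro-solver linearizes uptake per sweep; pathological
  parameter sets (e.g. near-discontinuous uptake at $\mu = 0$ over large
  regions) could slow convergence, which is why the residual is always
  checked against the true Monod rates and non-convergence is an error.
* Composition statistics at the fixture's 100-cell inoculum carry neutral
  drift of a few weight-percent; replicate seeds are the intended remedy.
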