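Package: aggsim
Title: Multiscale Simulation of Microbial Aggregates in Chemostat Culture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-tier simulator for niche competition among nitrifying guilds
    in continuous culture. A well-mixed chemostat model integrates coupled
    Monod-with-maintenance growth and solute mass balances to steady state,
    and an individual-based aggregate model resolves cells as discrete agents
    inside a 2-D aggregate and diffusive boundary layer, with a pseudo-steady
    state reaction-diffusion solver for the local solute fields and a
    multiscale coupler (representative-volume scale-up, fixed or dynamic
    boundary conditions) linking the aggregate to the bulk liquid. Ships a
    complete-ammonia-oxidizer versus canonical ammonia-oxidizer competition
    scenario in which the two guilds share identical kinetics and differ only
    in growth yield.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    yaml,
    graphics,
    grDevices,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
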