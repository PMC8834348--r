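Package: raftdyn
Title: Simulation and Inference of Raft-Nanodomain-Confined Membrane Diffusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to simulate and quantify the lateral dynamics of membrane
    probes that transiently partition into raft nanodomains. Provides a
    particle-level Monte Carlo simulator of two-dimensional diffusion in a
    periodic membrane containing circular trapping domains, a virtual
    confocal detector and multi-tau correlator that turn trajectories into
    fluorescence autocorrelation curves, fitting of the two-dimensional
    lateral diffusion model to extract diffusion times, construction of
    spot-variation FCS diffusion laws (confinement intercept t0 and
    effective diffusion coefficient D_eff with regime classification),
    and simulation plus fitting of fluorescence recovery after
    photobleaching (FRAP) curves for circular bleach regions (half-time of
    recovery and mobile fraction). Condition presets emulate measurements
    on erythroid cells with and without the raft-organizing scaffold
    protein MPP1.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
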