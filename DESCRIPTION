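Package: permeon
Title: Ion-Binding State Analysis of Single-File Ion Channel Permeation
Version: 0.1.0
Authors@R:
    person("Permeon", "Developers", email = "permeon@example.org",
           role = c("aut", "cre"))
Description: Discretizes one-dimensional potassium-ion trajectories along a
    channel pore axis into binding-site occupancy states (S0-S6), builds
    state-transition graphs with influx/efflux edge annotation, detects
    completed permeation events with back-running rejection, classifies each
    conduction as push (III-IV-III, four-ion intermediate) or pull
    (III-II-III, two-ion intermediate), and computes single-channel currents
    with local block bootstrap errors, occupancy free-energy differences and
    intermediate-state lifetimes. Includes a kinetic Monte Carlo generator of
    single-file hopping trajectories with exact ground-truth event logs for
    validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
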