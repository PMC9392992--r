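Package: coldchainr
Title: Two-Stage Route Optimization and Discrete-Event Simulation for
    Last-Mile Vaccine Cold-Chain Logistics
Version: 0.1.0
Authors@R:
    person("Coldchain", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Decision support for last-mile distribution of temperature-
    sensitive vaccines from a regional depot to municipal vaccination
    centers. Stage one solves a heterogeneous-fleet capacitated vehicle
    routing problem (exact dynamic programming for small instances, a
    Clarke-Wright savings heuristic with 2-opt and relocate improvement at
    scale) to produce milk-run plans; stage two executes those plans in a
    discrete-event simulator with stochastic travel speeds and handling
    times, weekly order epochs, shipping calendars, less-than-truckload
    dispatch, and total-backorder semantics. Monte-Carlo replication
    summarises service level, lead time, transportation cost, and CO2
    emissions per scenario, with paired common-random-number comparisons
    across fleet configurations and a center-of-gravity greenfield siting
    tool. A synthetic-instance generator emulates a Norwegian-county-like
    geography and supply-driven weekly dose allocation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
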