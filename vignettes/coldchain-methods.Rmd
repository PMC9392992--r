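---
title: "Methods: two-stage routing and simulation for last-mile vaccine logistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage routing and simulation for last-mile vaccine logistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During a supply-driven vaccination campaign, a regional depot must push
weekly dose allotments to dozens of municipal vaccination centers under cold
chain constraints. Decisions about the distribution-center (DC) location,
fleet size and fleet composition trade off three sustainability dimensions:
societal (on-time delivery against each customer group's expected lead time,
ELT), economic (transportation cost) and environmental (CO2 emissions).
`coldchainr` implements a two-stage decision-support pipeline for this
setting:

1. **Route optimization.** A heterogeneous-fleet capacitated vehicle routing
   problem (CVRP): minimize $\sum_{i,j,k} c_k d_{ij} x_{ijk}$ over binary arc
   variables, subject to each center being visited exactly once by one
   vehicle, flow conservation, a per-tour capacity constraint, a per-tour
   range limit $D_k$, and Dantzig–Fulkerson–Johnson (DFJ) subtour
   elimination. In the operational *unit/stop-limit* reading of capacity the
   per-customer demand is set to 1 and the right-hand side becomes the
   maximum number of stops per milk run (default 10), which favors
   responsiveness; the *volume* reading bounds the dose load by the
   vehicle's converted cargo volume (600 doses/m³ by default).
2. **Discrete-event + Monte-Carlo simulation.** The optimized milk runs are
   executed over the planning horizon with weekly order epochs, a
   Monday–Friday 06:00–15:00 shipping window, stochastic handling times and
   travel speeds, less-than-truckload dispatch, and total-backorder
   semantics. Thirty replications per scenario (the study's choice) give
   t-based confidence intervals on the KPIs.

## Stage 1: solver design

**Exact solver.** No MILP solver is available in the deployment environment,
so the exact method is a dynamic program that is provably optimal for the
instance sizes it accepts (default ceiling 15 customers): a Held–Karp
recursion yields the optimal tour length for *every* customer subset, each
subset is priced with the cheapest vehicle type whose range and capacity
admit its optimal tour, and a set-partition DP over subsets selects the
optimal collection of tours. Because any suboptimal stop order only
lengthens a tour (shrinking the set of feasible types and raising cost),
pricing the optimal order is sufficient. DFJ separation
(`separate_subtours()`) is retained as a standalone certified check used by
`validate_route_plan()`: it returns one cut per depot-disconnected component
of an integer arc solution.

**Heuristic.** Above the ceiling, Clarke–Wright parallel savings constructs
routes under the stop-limit/volume and range constraints, followed by
intra-route 2-opt and inter-route single-customer relocation to a fixed
point. Both solvers are deterministic: savings ties break by customer id,
and reported routes are canonically oriented (smaller endpoint first) and
sorted. The exact solver's tie-break among equal-cost optima is the DP's
fixed enumeration order rather than a global lexicographic minimum; tests
rely on determinism and on objective equality with an independent
enumeration oracle.

**Vehicle-type availability per group.** The three network models fix a
group-to-type policy: models 1–2 serve the near group with the
battery-electric e-NV200 (300 km range) and the far group with the NV200;
model 3 uses NV200 / VW Transporter. On geographies where some near-group
centers lie beyond the EV's round-trip range — which happens routinely with
a corner depot and a county-scale bounding box — a literal single-type
assignment makes stage 1 infeasible. The package's design choice is to admit
scenario-fleet types of *strictly larger range* as fallback within a group;
since the assigned type is also the cheapest per km, the objective keeps it
wherever its range permits. This mirrors the battery-limit behavior the
study itself reports qualitatively (EVs only pay off within a short radius)
while keeping every scenario runnable.

**Greenfield siting.** `greenfield_location()` computes the weighted
geometric median of the centers by Weiszfeld iteration on an equirectangular
projection about the weighted centroid, stopping when the move drops below
1 m (objective provably non-increasing; a 1 m grid-search oracle verifies
optimality in tests to within 0.1%).

## Stage 2: simulator semantics

Time is measured in minutes from 00:00 of the horizon start (default
2020-12-28, a Monday, through 2021-03-15 — twelve weekly order epochs).
Semantics chosen where the source material is silent:

- *Departures, not tours, are window-constrained.* A milk run cannot pause,
  so a trip departing at 14:55 completes past 15:00.
- *One speed draw per leg* (triangular 40/50/70 km/h by default), one
  outbound draw (U(20,30) min) per trip, one inbound draw (U(10,20) min) per
  stop; the vehicle waits during stop processing. All draws are rounded to
  the nearest second to avoid float-order sensitivity.
- *Backorders are total*: unfilled doses persist and merge with later weekly
  orders. Service is oldest-order-first, then ascending center id. Trips
  repeat on a route until its backlog clears, each load split across stops
  proportionally with largest-remainder rounding.
- *Fleet semantics*: a physical vehicle may run several tours (30 min
  turnaround), and the EV's range resets each tour (battery swap/recharge
  assumed). Stage 1 bounds routes by available *types*; fleet *counts* bind
  only in the simulator.
- *Horizon accounting*: no trip departs at or after the end instant (end
  date + 1 day, 00:00); in-flight trips complete and count as shipped, and
  backlog never loaded is reported undelivered, so delivered + undelivered
  equals demanded exactly in every replication.

**Common random numbers.** Each planned route owns an RNG substream derived
from the replication seed and the route index, and every trip consumes a
fixed-length draw block. Scenarios that share a plan (e.g. a fleet-size
ladder within one model) therefore see identical route-level noise, which
makes paired comparisons variance-free in the noise dimension and the
fleet-size monotonicity check sharp. Replication seeds derive from
`(base_seed, scenario, replication)` via a documented linear hash
(`derive_seed()`); paired mode keys all scenarios to one stream.

## The synthetic world

The study's weekly demand table and road distances are not public, so the
generator emulates their statistical shape rather than their values:

- 46 centers uniform in a county-like bounding box (lat 60.0–62.7, lon
  9.5–12.5), depot at the Oslo-like corner (59.913, 10.752); the model-2 DC
  defaults to the Hamar-like interior point (60.794, 11.068).
- Adult population 301,975 split by a normalized gamma (concentration 0.8,
  heavy-tailed like municipality sizes); the five most populous centers are
  flagged high-infection and receive a 20% dose uplift, matching the
  allocation policy's "+20% to the five hardest-hit municipalities" rule
  (which municipalities received it is not public; most-populous is the
  package's choice).
- Weekly supply `4000·1.05^w` doses times lognormal(0, 0.25) noise, w =
  0..11, allocated proportionally to uplifted population with per-center
  lognormal share noise and largest-remainder conservation. The base and
  growth are the package's choice of a realistic early-2021 series: the
  region holds ~7% of the national population and national weekly deliveries
  were in the tens of thousands; the resulting ~64k doses over 12 weeks
  (~21% of the adult population) is in the right range for that phase.
- Distances are great-circle × circuity 1.3 (tagged on the matrix). Real
  road routing, clustering of municipalities along valleys, and the
  ten-region administrative structure are *not* modeled; green tests
  establish the pipeline's internal correctness and directional behavior,
  not the study's printed KPI values.

## Numerical choices and degenerate inputs

- Shipping window is closed-left, open-right; a candidate departure at
  exactly 15:00 rolls to the next shipping day.
- Largest-remainder ties go to the larger fractional remainder, then the
  smaller center id.
- Service level on an empty log is 1.0 with a warning (no late deliveries
  occurred); lead-time statistics on an empty log are an error.
- Service level and mean lead time are dose-weighted by default
  ("products" read as doses); a per-shipment variant is a switch.
- The fixed 1500 NOK dispatch cost is charged per trip by default; a
  per-stop basis exists because the source tabulates the unit as NOK/stop
  while describing a constant per-dispatch driver cost.
- `capacity_in_doses()` floors; a 0 m³ vehicle has capacity 0 and is
  rejected by the simulator.

## Known limitations

- The exact solver is exponential (by design) and refuses instances above
  its ceiling instead of degrading silently.
- Uniform spatial placement understates route-sharing opportunities
  relative to valley-clustered real municipalities, so absolute costs and
  service levels are not comparable to the study's table — only directions
  and identities are.
- Time-window VRP variants, split deliveries, vehicle breakdowns,
  temperature excursions and reverse logistics are out of scope.
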