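# Independent oracles and fixture builders shared across test files.

# Spherical-law-of-cosines great-circle distance: a deliberately different
# formulation than the implementation under test.
slc_km <- function(lat1, lon1, lat2, lon2, R = 6371) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  arg <- sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl)
  R * acos(pmin(1, pmax(-1, arg)))
}

# Random small instance in a Norway-like box; groups relative to the depot.
mk_random_instance <- function(n, seed, doses = NULL) {
  set.seed(seed)
  loc <- make_locations(
    0:n, c("dc", paste0("c", 1:n)),
    c(59.9, runif(n, 60, 61.5)), c(10.75, runif(n, 9.8, 12)),
    c("depot", rep("center", n)),
    c(0, sample(500:5000, n, replace = TRUE)),
    rep(FALSE, n + 1), rep(NA_integer_, n + 1)
  )
  loc$group <- assign_customer_groups(loc)
  if (is.null(doses)) doses <- sample(100:900, n, replace = TRUE)
  dem <- data.frame(week = 0L, center_id = 1:n, doses = doses)
  make_instance(loc, dem, default_vehicles())
}

# n customers on a line going north, `spacing` km apart, first one `spacing`
# km from the depot (circuity 1 so matrix distances are exact haversines).
mk_line_instance <- function(n, spacing = 20) {
  deg_per_km <- 1 / (6371 * pi / 180)
  lat <- 59.9 + (0:n) * spacing * deg_per_km
  loc <- make_locations(
    0:n, c("dc", paste0("c", 1:n)), lat, rep(10.75, n + 1),
    c("depot", rep("center", n)), c(0, rep(1000, n)),
    rep(FALSE, n + 1), c(NA, rep(1L, n))
  )
  dem <- data.frame(week = 0L, center_id = 1:n, doses = rep(100L, n))
  make_instance(loc, dem, default_vehicles(), circuity = 1)
}

# Exhaustive-enumeration CVRP oracle: branch over the subset containing the
# first unrouted customer and all stop orders; prices each tour with the
# cheapest feasible type. Tractable for n <= 7.
oracle_cvrp <- function(inst, cfg) {
  loc <- inst$locations
  cust <- loc$id[loc$role == "center"]
  veh <- inst$vehicles
  if (!is.null(cfg$vehicle_types)) veh <- veh[match(cfg$vehicle_types, veh$name), ]
  if (cfg$capacity_mode == "unit_stop_limit") {
    q <- stats::setNames(rep(1, length(cust)), cust)
    cap <- rep(cfg$stop_limit, nrow(veh))
  } else {
    q <- stats::setNames(vapply(cust, function(id) {
      max(c(0, inst$demand$doses[inst$demand$center_id == id]))
    }, numeric(1)), cust)
    cap <- capacity_in_doses(veh, inst$doses_per_m3)
  }
  d <- inst$distances
  price <- function(stops) {
    len <- route_length(stops, d)
    load <- sum(q[as.character(stops)])
    f <- which(veh$range_km + 1e-9 >= len & cap + 1e-9 >= load)
    if (!length(f)) return(Inf)
    min(veh$var_cost_per_km[f]) * len
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(t) c(v[i], t))
    }))
  }
  best <- Inf
  recurse <- function(remaining, cost) {
    if (cost >= best) return(invisible())
    if (!length(remaining)) { best <<- min(best, cost); return(invisible()) }
    a <- remaining[1]; rest <- remaining[-1]
    for (k in 0:length(rest)) {
      combs <- if (k == 0) list(integer(0)) else
        utils::combn(rest, k, simplify = FALSE)
      for (comb in combs) {
        rc <- min(vapply(perms(c(a, comb)), price, numeric(1)))
        if (is.finite(rc)) recurse(setdiff(rest, comb), cost + rc)
      }
    }
  }
  recurse(cust, 0)
  best
}

# Single-type catalogue helpers for constructing controlled simulations.
one_vehicle <- function(name = "NV200", capacity_m3 = 2.1, range_km = 1000,
                        speed = c(40, 50, 70), var_cost = 8, emission = 131) {
  data.frame(name = name, capacity_m3 = capacity_m3, range_km = range_km,
             speed_min = speed[1], speed_mode = speed[2], speed_max = speed[3],
             var_cost_per_km = var_cost, fixed_cost = 1500,
             emission_g_per_km = emission, stringsAsFactors = FALSE)
}

# Instance with one center and an exact 100-km depot distance (the distance
# matrix is overwritten so the deterministic trace is exact).
mk_trace_instance <- function(doses = 100, weeks = 0L, speed = c(50, 50, 50)) {
  loc <- make_locations(0:1, c("dc", "c1"), c(59.9, 60.8), c(10.75, 10.75),
                        c("depot", "center"), c(0, 1000), c(FALSE, FALSE),
                        c(NA, 1L))
  dem <- data.frame(week = weeks, center_id = 1L,
                    doses = rep(doses, length(weeks)))
  inst <- make_instance(loc, dem, one_vehicle(speed = speed),
                        elt_days = c("1" = 1, "2" = 2))
  inst$distances[] <- matrix(c(0, 100, 100, 0), 2, 2)
  inst
}

# Plan with a single route over the given stops.
mk_plan <- function(inst, stops, type = "NV200") {
  plan <- list(routes = list(list(vehicle_type = type,
                                  stops = as.integer(stops))))
  plan$routes[[1]]$length_km <- route_length(plan$routes[[1]]$stops,
                                             inst$distances)
  plan$objective_nok_km <- NA_real_
  plan$optimality_tag <- "manual"
  class(plan) <- "cc_route_plan"
  plan
}

deterministic_sim <- function(fleet, ...) {
  sim_config(outbound = c(25, 25), inbound = c(15, 15), fleet = fleet, ...)
}
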