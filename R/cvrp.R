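#' Configuration for the route optimizer
#'
#' Two capacity readings of the fleet-capacity constraint are supported:
#' `"unit_stop_limit"` treats every customer as one unit and caps the number
#' of stops per tour (the operational choice for responsiveness; default
#' limit 10 stops), `"volume"` caps the dose load per tour by the vehicle's
#' converted cargo volume.
#'
#' @param capacity_mode `"unit_stop_limit"` or `"volume"`.
#' @param stop_limit Maximum stops per tour in unit mode (default 10).
#' @param customers Integer ids of the customers to plan; `NULL` = all
#'   centers of the instance.
#' @param vehicle_types Character vector of catalogue type names available to
#'   the planner, in preference order; `NULL` = whole catalogue.
#' @param exact_ceiling Largest customer count accepted by the exact solver
#'   (default 15).
#' @return A list of class `cc_cvrp_config`.
#' @export
cvrp_config <- function(capacity_mode = c("unit_stop_limit", "volume"),
                        stop_limit = 10, customers = NULL,
                        vehicle_types = NULL, exact_ceiling = 15) {
  capacity_mode <- match.arg(capacity_mode)
  stopifnot(stop_limit >= 1, exact_ceiling >= 1)
  structure(list(capacity_mode = capacity_mode, stop_limit = stop_limit,
                 customers = customers, vehicle_types = vehicle_types,
                 exact_ceiling = exact_ceiling),
            class = "cc_cvrp_config")
}

# Resolve config against an instance: customer ids, demand vector q,
# and per-type cost/capacity/range in the chosen capacity mode.
resolve_cvrp <- function(instance, cfg) {
  loc <- instance$locations
  customers <- cfg$customers
  if (is.null(customers)) customers <- loc$id[loc$role == "center"]
  customers <- sort(as.integer(customers))
  if (!all(customers %in% loc$id[loc$role == "center"])) {
    stop("unknown customer id in cvrp config", call. = FALSE)
  }
  veh <- instance$vehicles
  tn <- cfg$vehicle_types
  if (is.null(tn)) tn <- veh$name
  if (!all(tn %in% veh$name)) {
    stop("unknown vehicle type: ", paste(setdiff(tn, veh$name), collapse = ", "),
         call. = FALSE)
  }
  veh <- veh[match(tn, veh$name), , drop = FALSE]
  if (cfg$capacity_mode == "unit_stop_limit") {
    q <- rep(1, length(customers))
    cap <- rep(cfg$stop_limit, nrow(veh))
  } else {
    q <- stage1_demand(instance, customers)
    cap <- capacity_in_doses(veh, instance$doses_per_m3)
  }
  list(customers = customers, q = q, veh = veh, cap = as.numeric(cap))
}

# Stage-1 per-customer load in volume mode: the peak weekly demand, so a
# plan feasible here is volume-feasible in every week.
stage1_demand <- function(instance, customers) {
  vapply(customers, function(id) {
    d <- instance$demand$doses[instance$demand$center_id == id]
    if (length(d)) max(d) else 0
  }, numeric(1))
}

#' Tour length of a stop sequence
#'
#' Depot (node 0) to first stop, consecutive legs, last stop back to depot.
#'
#' @param stops Integer customer ids in visiting order.
#' @param dmat Distance matrix of the instance.
#' @return Length in km.
#' @export
route_length <- function(stops, dmat) {
  idx <- c(1L, stops + 1L, 1L)
  sum(dmat[cbind(idx[-length(idx)], idx[-1])])
}

route_legs <- function(stops, dmat) {
  idx <- c(1L, stops + 1L, 1L)
  dmat[cbind(idx[-length(idx)], idx[-1])]
}

new_route_plan <- function(routes, veh, dmat, optimality_tag) {
  routes <- lapply(routes, function(r) {
    if (r$stops[1] > r$stops[length(r$stops)]) r$stops <- rev(r$stops)
    r$length_km <- route_length(r$stops, dmat)
    r
  })
  routes <- routes[order(vapply(routes, function(r) r$stops[1], numeric(1)))]
  obj <- sum(vapply(routes, function(r) {
    veh$var_cost_per_km[match(r$vehicle_type, veh$name)] * r$length_km
  }, numeric(1)))
  structure(list(routes = routes, objective_nok_km = obj,
                 optimality_tag = optimality_tag),
            class = "cc_route_plan")
}

#' @export
print.cc_route_plan <- function(x, ...) {
  cat(sprintf("<cc_route_plan> %d routes, objective %.1f NOK (distance-rate part), %s\n",
              length(x$routes), x$objective_nok_km, x$optimality_tag))
  for (i in seq_along(x$routes)) {
    r <- x$routes[[i]]
    cat(sprintf("  [%d] %-14s %6.1f km | %s\n", i, r$vehicle_type,
                r$length_km, paste(r$stops, collapse = " -> ")))
  }
  invisible(x)
}

#' Exact heterogeneous-fleet CVRP solver
#'
#' Minimises the distance-rate objective `sum c_k d_ij x_ijk` subject to
#' single-visit degree and flow constraints, the capacity constraint in the
#' configured mode, the per-tour range limit of the vehicle type serving the
#' tour, and subtour elimination. Exact by dynamic programming over customer
#' subsets (optimal tour per subset, then an optimal set partition into
#' tours); each tour is priced with the cheapest type whose range and
#' capacity admit it. Deterministic: ties are broken by the DP's fixed
#' enumeration order and routes are reported in canonical orientation
#' (smaller endpoint first) sorted by first stop.
#'
#' @param instance A `cc_instance`.
#' @param cfg A [cvrp_config()].
#' @return A `cc_route_plan` with `optimality_tag = "exact"`.
#' @export
solve_cvrp_exact <- function(instance, cfg = cvrp_config()) {
  rc <- resolve_cvrp(instance, cfg)
  n <- length(rc$customers)
  if (n > cfg$exact_ceiling) {
    stop(sprintf("%d customers exceeds the exact-mode ceiling (%d); use solve_cvrp_heuristic()",
                 n, cfg$exact_ceiling), call. = FALSE)
  }
  res <- cvrp_exact_dp(instance$distances, as.integer(rc$customers), rc$q,
                       rc$veh$var_cost_per_km, rc$cap, rc$veh$range_km)
  if (!isTRUE(res$feasible)) {
    stop(infeasibility_message(res$infeasible_customer), call. = FALSE)
  }
  routes <- Map(function(stops, type) {
    list(vehicle_type = rc$veh$name[type], stops = as.integer(stops))
  }, res$routes, res$types)
  new_route_plan(routes, instance$vehicles, instance$distances, "exact")
}

infeasibility_message <- function(customer) {
  if (is.na(customer)) {
    "infeasible: no partition of the customers into feasible tours exists"
  } else {
    sprintf("infeasible: customer %d cannot be served by any available vehicle type (round trip exceeds every range or capacity)",
            customer)
  }
}

#' Separate violated subtour-elimination cuts
#'
#' Given the arc set of a degree-feasible integer solution, returns one cut
#' (the customer set of a component) for every connected component that does
#' not contain the depot; the empty list certifies that every tour reaches
#' the depot.
#'
#' @param arcs Two-column matrix or data frame of arcs `(from, to)` in node
#'   ids (depot = 0).
#' @param depot Depot node id (default 0).
#' @return List of integer vectors (sorted customer ids), one per violated
#'   cut.
#' @export
separate_subtours <- function(arcs, depot = 0) {
  arcs <- as.matrix(arcs)
  if (nrow(arcs) == 0) return(list())
  nodes <- sort(unique(c(arcs[, 1], arcs[, 2])))
  adj <- split(c(arcs[, 2], arcs[, 1]), c(arcs[, 1], arcs[, 2]))
  comp_of <- setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (s in nodes) {
    if (!is.na(comp_of[as.character(s)])) next
    cid <- cid + 1L
    queue <- s
    comp_of[as.character(s)] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[as.character(v)]]) {
        if (is.na(comp_of[as.character(w)])) {
          comp_of[as.character(w)] <- cid
          queue <- c(queue, w)
        }
      }
    }
  }
  depot_comp <- if (as.character(depot) %in% names(comp_of)) {
    comp_of[as.character(depot)]
  } else NA_integer_
  cuts <- list()
  for (k in seq_len(cid)) {
    if (!is.na(depot_comp) && k == depot_comp) next
    members <- as.integer(names(comp_of)[comp_of == k])
    cuts[[length(cuts) + 1L]] <- sort(setdiff(members, depot))
  }
  cuts
}

plan_arcs <- function(plan) {
  do.call(rbind, lapply(plan$routes, function(r) {
    seqn <- c(0L, r$stops, 0L)
    cbind(from = seqn[-length(seqn)], to = seqn[-1])
  }))
}

#' Check a route plan against every model constraint
#'
#' Violations are returned as data, not raised: single visit per customer
#' (degree/flow), stop-limit or volume capacity, per-tour range of the
#' serving vehicle type, tour-length bookkeeping, and depot connectivity
#' (subtour-freeness, certified via [separate_subtours()]).
#'
#' @param plan A `cc_route_plan`.
#' @param instance The instance it was built for.
#' @param cfg The [cvrp_config()] used.
#' @return Character vector of violation messages; empty if the plan is
#'   feasible.
#' @export
validate_route_plan <- function(plan, instance, cfg = cvrp_config()) {
  rc <- resolve_cvrp(instance, cfg)
  v <- character(0)
  all_stops <- unlist(lapply(plan$routes, `[[`, "stops"))
  tab <- table(factor(all_stops, levels = rc$customers))
  for (id in names(tab)[tab > 1]) {
    v <- c(v, sprintf("customer %s multiplicity %d", id, tab[[id]]))
  }
  for (id in names(tab)[tab == 0]) {
    v <- c(v, sprintf("customer %s unserved", id))
  }
  extra <- setdiff(unique(all_stops), rc$customers)
  if (length(extra)) {
    v <- c(v, sprintf("unexpected stop(s): %s", paste(extra, collapse = ", ")))
  }
  veh <- instance$vehicles
  for (i in seq_along(plan$routes)) {
    r <- plan$routes[[i]]
    if (length(r$stops) == 0) { v <- c(v, sprintf("route %d empty", i)); next }
    if (0 %in% r$stops) v <- c(v, sprintf("route %d visits the depot", i))
    ti <- match(r$vehicle_type, veh$name)
    if (is.na(ti)) {
      v <- c(v, sprintf("route %d: unknown vehicle type '%s'", i,
                        r$vehicle_type))
      next
    }
    len <- route_length(r$stops, instance$distances)
    if (!is.null(r$length_km) && abs(len - r$length_km) > 1e-6) {
      v <- c(v, sprintf("route %d: stored length %.3f km != recomputed %.3f km",
                        i, r$length_km, len))
    }
    if (cfg$capacity_mode == "unit_stop_limit") {
      if (length(r$stops) > cfg$stop_limit) {
        v <- c(v, sprintf("route %d: %d stops exceeds stop limit %d (capacity)",
                          i, length(r$stops), cfg$stop_limit))
      }
    } else {
      load <- sum(rc$q[match(r$stops, rc$customers)])
      cap <- capacity_in_doses(veh[ti, ], instance$doses_per_m3)
      if (load > cap) {
        v <- c(v, sprintf("route %d (%s): load %g doses exceeds capacity %d",
                          i, r$vehicle_type, load, cap))
      }
    }
    if (len > veh$range_km[ti] + 1e-9) {
      v <- c(v, sprintf("route %d (%s): %.1f km exceeds range %g km",
                        i, r$vehicle_type, len, veh$range_km[ti]))
    }
  }
  cuts <- separate_subtours(plan_arcs(plan))
  for (cut in cuts) {
    v <- c(v, sprintf("subtour disconnected from depot: {%s}",
                      paste(cut, collapse = ", ")))
  }
  v
}
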