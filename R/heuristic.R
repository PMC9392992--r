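# Route cost under the cheapest feasible vehicle type; Inf when no available
# type has both the range and the capacity for the tour.
route_price <- function(len, load, veh, cap) {
  feas <- which(veh$range_km + 1e-9 >= len & cap + 1e-9 >= load)
  if (!length(feas)) return(list(cost = Inf, type = NA_character_))
  k <- feas[which.min(veh$var_cost_per_km[feas])]
  list(cost = veh$var_cost_per_km[k] * len, type = veh$name[k])
}

#' Clarke-Wright savings heuristic with 2-opt and relocate improvement
#'
#' Scalable fallback for instances above the exact-mode ceiling. Parallel
#' savings merges seed single-customer tours while the merged tour stays
#' feasible for some available vehicle type; each tour is then improved by
#' intra-route 2-opt and inter-route single-customer relocation until no
#' move lowers total cost. Deterministic for a given instance (savings ties
#' broken by customer id).
#'
#' @inheritParams solve_cvrp_exact
#' @return A `cc_route_plan` with `optimality_tag = "heuristic"`.
#' @export
solve_cvrp_heuristic <- function(instance, cfg = cvrp_config()) {
  rc <- resolve_cvrp(instance, cfg)
  d <- instance$distances
  cust <- rc$customers
  n <- length(cust)
  qmap <- setNames(rc$q, cust)

  price <- function(stops) {
    route_price(route_length(stops, d), sum(qmap[as.character(stops)]),
                rc$veh, rc$cap)
  }
  for (i in seq_len(n)) {
    if (!is.finite(price(cust[i])$cost)) {
      stop(infeasibility_message(cust[i]), call. = FALSE)
    }
  }
  routes <- lapply(cust, function(id) id)

  if (n > 1) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    sav <- d[cbind(1, cust[pairs[, 1]] + 1)] + d[cbind(1, cust[pairs[, 2]] + 1)] -
      d[cbind(cust[pairs[, 1]] + 1, cust[pairs[, 2]] + 1)]
    ord <- order(-sav, cust[pairs[, 1]], cust[pairs[, 2]])
    route_of <- setNames(seq_len(n), cust)
    for (p in ord) {
      i <- cust[pairs[p, 1]]; j <- cust[pairs[p, 2]]
      ri <- route_of[[as.character(i)]]; rj <- route_of[[as.character(j)]]
      if (ri == rj) next
      a <- routes[[ri]]; b <- routes[[rj]]
      merged <- NULL
      if (a[length(a)] == i && b[1] == j) merged <- c(a, b)
      else if (b[length(b)] == j && a[1] == i) merged <- c(b, a)
      else if (a[1] == i && b[1] == j) merged <- c(rev(a), b)
      else if (a[length(a)] == i && b[length(b)] == j) merged <- c(a, rev(b))
      if (is.null(merged)) next
      if (cfg$capacity_mode == "unit_stop_limit" &&
          length(merged) > cfg$stop_limit) next
      if (!is.finite(price(merged)$cost)) next
      routes[[ri]] <- merged
      routes[[rj]] <- integer(0)
      route_of[as.character(merged)] <- ri
    }
    routes <- routes[vapply(routes, length, integer(1)) > 0]
  }

  routes <- improve_routes(routes, price, cfg)
  plan_routes <- lapply(routes, function(stops) {
    list(vehicle_type = price(stops)$type, stops = as.integer(stops))
  })
  new_route_plan(plan_routes, instance$vehicles, instance$distances,
                 "heuristic")
}

# Local search: intra-route 2-opt, then best-improvement single-customer
# relocation across routes; repeat to a fixed point (bounded passes).
improve_routes <- function(routes, price, cfg) {
  two_opt <- function(stops) {
    m <- length(stops)
    if (m < 3) return(stops)
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      base <- price(stops)$cost
      for (i in 1:(m - 1)) {
        for (j in (i + 1):m) {
          cand <- stops
          cand[i:j] <- rev(cand[i:j])
          if (price(cand)$cost < base - 1e-9) {
            stops <- cand; base <- price(cand)$cost; improved <- TRUE
          }
        }
      }
    }
    stops
  }
  for (pass in 1:50) {
    routes <- lapply(routes, two_opt)
    moved <- FALSE
    r_order <- seq_along(routes)
    for (ra in r_order) {
      stops_a <- routes[[ra]]
      for (s in stops_a) {
        if (!(s %in% routes[[ra]])) next
        from <- setdiff(routes[[ra]], s)
        base <- price(routes[[ra]])$cost
        best_gain <- 1e-9; best <- NULL
        for (rb in seq_along(routes)) {
          if (rb == ra) next
          tgt <- routes[[rb]]
          if (cfg$capacity_mode == "unit_stop_limit" &&
              length(tgt) + 1 > cfg$stop_limit) next
          for (pos in 0:length(tgt)) {
            cand <- append(tgt, s, after = pos)
            new_cost <- price(from)$cost + price(cand)$cost
            old_cost <- base + price(tgt)$cost
            if (is.finite(new_cost) && old_cost - new_cost > best_gain) {
              best_gain <- old_cost - new_cost
              best <- list(rb = rb, cand = cand)
            }
          }
        }
        if (!is.null(best)) {
          routes[[ra]] <- from
          routes[[best$rb]] <- best$cand
          moved <- TRUE
        }
      }
    }
    routes <- routes[vapply(routes, length, integer(1)) > 0]
    if (!moved) break
  }
  routes
}

#' Solve the routing stage, choosing exact or heuristic mode
#'
#' @inheritParams solve_cvrp_exact
#' @param method `"auto"` (exact up to the config's ceiling, heuristic
#'   beyond), `"exact"`, or `"heuristic"`.
#' @return A `cc_route_plan`.
#' @export
solve_cvrp <- function(instance, cfg = cvrp_config(),
                       method = c("auto", "exact", "heuristic")) {
  method <- match.arg(method)
  rc <- resolve_cvrp(instance, cfg)
  if (method == "auto") {
    method <- if (length(rc$customers) <= cfg$exact_ceiling) "exact" else "heuristic"
  }
  if (method == "exact") solve_cvrp_exact(instance, cfg)
  else solve_cvrp_heuristic(instance, cfg)
}
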