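test_that("exact solver handles the single-customer and line instances", {
  inst <- mk_trace_instance()          # one center, exactly 100 km
  cfg <- cvrp_config(vehicle_types = "NV200")
  plan <- solve_cvrp_exact(inst, cfg)
  expect_equal(length(plan$routes), 1)
  expect_equal(plan$routes[[1]]$stops, 1L)
  expect_equal(plan$objective_nok_km, 8 * 200)  # NV200 at 8 NOK/km, 200 km
  expect_equal(plan$optimality_tag, "exact")

  line <- mk_line_instance(5, spacing = 20)
  cfg1 <- cvrp_config(vehicle_types = "NV200")
  ex <- solve_cvrp_exact(line, cfg1)
  expect_equal(ex$objective_nok_km, oracle_cvrp(line, cfg1))
  expect_length(validate_route_plan(ex, line, cfg1), 0)
})

test_that("exact solver reports range-infeasible customers and the size ceiling", {
  far <- mk_line_instance(2, spacing = 400)  # customer 2 sits 800 km out
  expect_error(solve_cvrp_exact(far, cvrp_config()),
               "infeasible: customer 2")
  inst <- mk_random_instance(6, seed = 2)
  expect_error(solve_cvrp_exact(inst, cvrp_config(exact_ceiling = 5)),
               "heuristic")
})

test_that("exact solver is deterministic and objective matches recomputation", {
  inst <- mk_random_instance(7, seed = 12)
  cfg <- cvrp_config(stop_limit = 3)
  p1 <- solve_cvrp_exact(inst, cfg)
  p2 <- solve_cvrp_exact(inst, cfg)
  expect_identical(p1, p2)
  veh <- inst$vehicles
  recomputed <- sum(vapply(p1$routes, function(r) {
    veh$var_cost_per_km[veh$name == r$vehicle_type] *
      route_length(r$stops, inst$distances)
  }, numeric(1)))
  expect_equal(p1$objective_nok_km, recomputed)
})

test_that("subtour separation matches an independent graph-traversal oracle", {
  # disconnected cycle {1,2,3} plus a depot tour
  arcs <- rbind(c(0, 4), c(4, 5), c(5, 0),
                c(1, 2), c(2, 3), c(3, 1))
  cuts <- separate_subtours(arcs)
  expect_equal(cuts, list(c(1L, 2L, 3L)))
  # a valid single tour -> no cuts
  tour <- cbind(0:4, c(1:4, 0))
  expect_length(separate_subtours(tour), 0)

  skip_if_not_installed("igraph")
  set.seed(33)
  for (i in 1:15) {
    # random degree-feasible solution: permutation cycles over 0..n
    n <- sample(5:12, 1)
    perm <- sample(0:n)
    arcs <- cbind(perm, c(perm[-1], perm[1]))
    # split into 1-3 cycles by cutting the permutation
    k <- sample(1:3, 1)
    cutpts <- sort(sample(seq_len(n), k - 1))
    pieces <- split(seq_len(n + 1), findInterval(seq_len(n + 1), cutpts + 1))
    arcs <- do.call(rbind, lapply(pieces, function(ix) {
      v <- perm[ix]
      cbind(v, c(v[-1], v[1]))
    }))
    cuts <- separate_subtours(arcs)
    g <- igraph::graph_from_edgelist(
      matrix(as.character(arcs), ncol = 2), directed = FALSE)
    comp <- igraph::components(g)$membership
    depot_comp <- comp[["0"]]
    expected <- lapply(setdiff(unique(comp), depot_comp), function(cc) {
      sort(as.integer(names(comp)[comp == cc]))
    })
    expect_setequal(cuts, expected)
  }
})

test_that("plan validation flags each constraint violation", {
  inst <- mk_random_instance(12, seed = 5)
  cfg <- cvrp_config(customers = 1:12)
  ok <- solve_cvrp_exact(inst, cfg)
  expect_length(validate_route_plan(ok, inst, cfg), 0)

  dup <- mk_plan(inst, c(1, 2, 3))
  dup$routes[[2]] <- list(vehicle_type = "NV200", stops = c(3L, 4L),
                          length_km = route_length(c(3L, 4L), inst$distances))
  v <- validate_route_plan(dup, inst, cvrp_config(customers = 1:4))
  expect_true(any(grepl("customer 3 multiplicity 2", v)))

  big <- mk_plan(inst, 1:11)
  v2 <- validate_route_plan(big, inst, cvrp_config(customers = 1:11))
  expect_true(any(grepl("11 stops exceeds stop limit 10", v2)))

  # e-NV200 on a 320-km tour violates its 300 km range
  line <- mk_line_instance(1, spacing = 160)
  ev <- mk_plan(line, 1, type = "e-NV200")
  v3 <- validate_route_plan(ev, line, cvrp_config(customers = 1))
  expect_true(any(grepl("exceeds range 300", v3)))
})

test_that("heuristic returns feasible plans bounded below by the exact optimum", {
  line <- mk_line_instance(1, spacing = 50)
  cfg <- cvrp_config(vehicle_types = "NV200")
  expect_equal(solve_cvrp_heuristic(line, cfg)$routes,
               solve_cvrp_exact(line, cfg)$routes)

  far <- mk_line_instance(2, spacing = 400)
  expect_error(solve_cvrp_heuristic(far, cvrp_config()),
               "infeasible: customer 2")

  inst46 <- synthetic_instance(seed = 1)
  cfg46 <- cvrp_config(vehicle_types = c("NV200"))
  h <- solve_cvrp_heuristic(inst46, cfg46)
  expect_length(validate_route_plan(h, inst46, cfg46), 0)
  expect_gte(length(h$routes), ceiling(46 / 10))  # pigeonhole on stop limit
})

test_that("auto mode dispatches on instance size", {
  small <- mk_random_instance(6, seed = 8)
  expect_equal(solve_cvrp(small, cvrp_config())$optimality_tag, "exact")
  big <- synthetic_instance(seed = 2)
  expect_equal(solve_cvrp(big, cvrp_config(vehicle_types = "NV200"))$optimality_tag,
               "heuristic")
})

test_that("greenfield location solves fixed-point, midpoint and matches a grid oracle", {
  single <- greenfield_location(61.2, 10.9)
  expect_equal(unname(single), c(61.2, 10.9))

  mid <- greenfield_location(c(60, 61), c(10.4, 10.4))
  expect_equal(unname(mid[1]), 60.5, tolerance = 1e-4)
  expect_equal(unname(mid[2]), 10.4, tolerance = 1e-6)

  set.seed(17)
  lat <- runif(10, 60, 62); lon <- runif(10, 9.5, 12); w <- runif(10, 1, 5)
  gf <- greenfield_location(lat, lon, w)
  obj <- function(p) sum(w * haversine_km(p[1], p[2], lat, lon))
  # grid-search oracle at ~1 m resolution refined around coarse optimum
  grid_best <- local({
    best <- c(mean(lat), mean(lon)); span <- c(1, 2)
    for (step in 1:5) {
      la <- seq(best[1] - span[1], best[1] + span[1], length.out = 21)
      lo <- seq(best[2] - span[2], best[2] + span[2], length.out = 21)
      gr <- expand.grid(la = la, lo = lo)
      vals <- mapply(function(a, b) obj(c(a, b)), gr$la, gr$lo)
      best <- unlist(gr[which.min(vals), ], use.names = FALSE)
      span <- span / 10
    }
    best
  })
  expect_lt((obj(gf) - obj(grid_best)) / obj(grid_best), 0.001)
  # Weiszfeld objective is non-increasing
  tr <- attr(gf, "objective_trace")
  expect_true(all(diff(tr) <= 1e-9))

  expect_error(greenfield_location(60, 10, weights = 0), "weights")
})

test_that("vehicle-type assignment follows the model mapping and overrides", {
  expect_equal(assign_vehicle_types(1),
               c("1" = "e-NV200", "2" = "NV200"))
  expect_equal(assign_vehicle_types(3),
               c("1" = "NV200", "2" = "VW Transporter"))
  ov <- c("1" = "VW Transporter", "2" = "VW Transporter")
  expect_equal(assign_vehicle_types(2, override = ov), ov)
  expect_error(assign_vehicle_types(4), "unknown model_id")
  expect_error(assign_vehicle_types(1, override = c("1" = "tractor",
                                                    "2" = "NV200")),
               "unknown vehicle type")
})
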