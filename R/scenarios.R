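#' Define a test scenario
#'
#' A scenario fixes the network model (1 = corner depot with mixed
#' EV/combustion fleet, 2 = relocated central DC with 1-day ELT for both
#' groups, 3 = corner depot, combustion-only fleet) and the fleet size per
#' vehicle type.
#'
#' @param id Scenario identifier.
#' @param model_id 1, 2 or 3.
#' @param fleet Named non-negative integer vector of vehicles per type; at
#'   least one vehicle in total.
#' @param sim_overrides Named list of [sim_config()] arguments to override.
#' @return A list of class `cc_scenario`.
#' @export
scenario <- function(id, model_id, fleet, sim_overrides = list()) {
  if (!model_id %in% 1:3) stop("model_id must be 1, 2 or 3", call. = FALSE)
  if (any(fleet < 0) || sum(fleet) < 1) {
    stop("fleet counts must be >= 0 with at least one vehicle", call. = FALSE)
  }
  structure(list(id = id, model_id = model_id, fleet = fleet,
                 sim_overrides = sim_overrides), class = "cc_scenario")
}

#' Deterministic seed derivation for replication streams
#'
#' `(base * 48271 + scenario * 1299721 + rep * 7919) mod (2^31 - 1)`, mapped
#' away from zero. Paired comparisons pass `scenario_key = 0` for every
#' scenario so replication `r` shares one common-random-number stream.
#'
#' @param base_seed Base integer seed.
#' @param scenario_key Scenario id, or 0 for paired streams.
#' @param rep Replication index (1-based).
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(base_seed, scenario_key, rep) {
  s <- ((base_seed %% 2147483647) * 48271 +
          scenario_key * 1299721 + rep * 7919) %% 2147483647
  as.integer(s + (s == 0))
}

# Hamar-like default DC for the relocated-network model.
MODEL2_DC <- c(lat = 60.794, lon = 11.068)

#' Prepare a scenario for execution: network model, stage-1 plan, sim config
#'
#' For model 2 the depot is moved to the central DC (the fixed Hamar-like
#' default, or the greenfield center of gravity of demand when `gfa = TRUE`),
#' distances are rebuilt, customer groups are re-assigned relative to the new
#' DC, and both groups get a 1-day ELT. Routing is per customer group with
#' the model's assigned vehicle type; scenario-fleet types of strictly larger
#' range are admitted as fallback so that centers beyond the assigned type's
#' round-trip range remain servable (the cheaper assigned type still wins
#' wherever its range permits).
#'
#' @param instance A `cc_instance`.
#' @param scen A [scenario()].
#' @param gfa Recompute the model-2 DC by greenfield analysis.
#' @param method Stage-1 solver mode, see [solve_cvrp()].
#' @param stop_limit Route capacity in stops (default 10).
#' @return List: possibly re-anchored `instance`, combined `plan`, simulation
#'   `config`, and the group-to-type map.
#' @export
stage_scenario <- function(instance, scen, gfa = FALSE, method = "auto",
                           stop_limit = 10) {
  inst <- instance
  if (scen$model_id == 2) {
    dc <- if (gfa) {
      cen <- inst$locations[inst$locations$role == "center", ]
      w <- stage1_demand(inst, cen$id)
      if (all(w == 0)) w <- rep(1, nrow(cen))
      greenfield_location(cen$lat, cen$lon, w)
    } else MODEL2_DC
    loc <- inst$locations
    loc$lat[loc$role == "depot"] <- dc[["lat"]]
    loc$lon[loc$role == "depot"] <- dc[["lon"]]
    loc$group <- assign_customer_groups(loc)
    inst <- make_instance(loc, inst$demand, inst$vehicles,
                          elt_days = c("1" = 1, "2" = 1),
                          horizon = inst$horizon,
                          doses_per_m3 = inst$doses_per_m3,
                          circuity = inst$circuity)
  }
  vmap <- assign_vehicle_types(scen$model_id, inst$vehicles)
  veh <- inst$vehicles
  fleet_types <- names(scen$fleet)[scen$fleet > 0]
  routes <- list()
  tags <- character(0)
  for (g in c("1", "2")) {
    ids <- inst$locations$id[inst$locations$role == "center" &
                               !is.na(inst$locations$group) &
                               inst$locations$group == as.integer(g)]
    if (!length(ids)) next
    assigned <- vmap[[g]]
    rng_assigned <- veh$range_km[veh$name == assigned]
    fallback <- veh$name[veh$name %in% fleet_types &
                           veh$range_km > rng_assigned]
    cfg <- cvrp_config(stop_limit = stop_limit, customers = ids,
                       vehicle_types = c(assigned, fallback))
    p <- solve_cvrp(inst, cfg, method = method)
    routes <- c(routes, p$routes)
    tags <- c(tags, p$optimality_tag)
  }
  plan <- new_route_plan(routes, veh, inst$distances,
                         if (all(tags == "exact")) "exact" else "heuristic")
  fleet <- setNames(rep(0L, nrow(veh)), veh$name)
  fleet[names(scen$fleet)] <- scen$fleet
  cfg_args <- c(list(start = inst$horizon[1], end = inst$horizon[2],
                     fleet = fleet), scen$sim_overrides)
  config <- do.call(sim_config, cfg_args)
  list(instance = inst, plan = plan, config = config, vmap = vmap)
}

#' Run the full two-stage pipeline for one scenario
#'
#' Stage 1 routes the (model-specific) network; stage 2 executes the plan in
#' `n_reps` Monte-Carlo replications with seeds derived deterministically
#' from `base_seed` (see [derive_seed()]).
#'
#' @inheritParams stage_scenario
#' @param n_reps Number of replications (default 30).
#' @param base_seed Base seed.
#' @param paired Use the common (scenario-independent) seed stream.
#' @return List of class `cc_two_stage`: `plan`, per-replication `reports`,
#'   Monte-Carlo `summary`, the staged `instance`/`config`, and `scenario`.
#' @export
run_two_stage <- function(instance, scen, n_reps = 30, base_seed = 1,
                          gfa = FALSE, method = "auto", paired = FALSE) {
  staged <- stage_scenario(instance, scen, gfa = gfa, method = method)
  key <- if (paired) 0 else scen$id
  reports <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
    log <- run_replication(staged$instance, staged$plan, staged$config,
                           seed = derive_seed(base_seed, key, r))
    cbind(rep = r, kpi_report(log, staged$instance))
  }))
  structure(list(plan = staged$plan, reports = reports,
                 summary = aggregate_replications(reports),
                 instance = staged$instance, config = staged$config,
                 scenario = scen),
            class = "cc_two_stage")
}

#' @export
print.cc_two_stage <- function(x, ...) {
  cat(sprintf("<cc_two_stage> scenario %s (model %d): %d routes, %d replications\n",
              format(x$scenario$id), x$scenario$model_id,
              length(x$plan$routes), max(x$reports$rep)))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Compare scenarios under common or independent random numbers
#'
#' Runs every scenario on the same instance and reports per-scenario
#' Monte-Carlo summaries, pairwise mean deltas of the headline KPIs, and —
#' for fleet-nested scenario pairs within the same model — the per-paired-
#' replication service-level monotonicity verdict (larger fleets should
#' never serve worse under common random numbers).
#'
#' @param instance A `cc_instance`.
#' @param scenarios List of [scenario()] objects (>= 2).
#' @param n_reps Replications per scenario.
#' @param base_seed Base seed.
#' @param paired Use common random numbers across scenarios (default TRUE).
#' @param ... Passed to [run_two_stage()].
#' @return List of class `cc_comparison`: `runs`, `deltas`, `nested`,
#'   `paired`.
#' @export
compare_scenarios <- function(instance, scenarios, n_reps = 30,
                              base_seed = 1, paired = TRUE, ...) {
  if (length(scenarios) < 2) stop("need at least two scenarios", call. = FALSE)
  runs <- lapply(scenarios, function(s) {
    run_two_stage(instance, s, n_reps = n_reps, base_seed = base_seed,
                  paired = paired, ...)
  })
  ids <- vapply(scenarios, function(s) s$id, numeric(1))
  kpis <- c("service_level", "lead_mean_days", "lead_max_days", "cost_nok",
            "co2_g")
  mean_of <- function(run, k) run$summary$mean[run$summary$kpi == k]
  deltas <- do.call(rbind, do.call(c, lapply(seq_along(runs), function(i) {
    lapply(seq_along(runs), function(j) {
      if (j <= i) return(NULL)
      row <- data.frame(a = ids[i], b = ids[j])
      for (k in kpis) row[[paste0("delta_", k)]] <-
          mean_of(runs[[j]], k) - mean_of(runs[[i]], k)
      row
    })
  })))
  nested <- NULL
  for (i in seq_along(runs)) for (j in seq_along(runs)) {
    si <- scenarios[[i]]; sj <- scenarios[[j]]
    if (i == j || si$model_id != sj$model_id) next
    fi <- setNames(rep(0, 3), c("e-NV200", "NV200", "VW Transporter"))
    fj <- fi
    fi[names(si$fleet)] <- si$fleet
    fj[names(sj$fleet)] <- sj$fleet
    if (all(fi <= fj) && any(fi < fj)) {
      ok <- if (paired) {
        all(runs[[j]]$reports$service_level >=
              runs[[i]]$reports$service_level - 1e-12)
      } else NA
      nested <- rbind(nested, data.frame(
        smaller = ids[i], larger = ids[j], paired_monotone = ok))
    }
  }
  structure(list(runs = runs, deltas = deltas, nested = nested,
                 paired = paired),
            class = "cc_comparison")
}

#' Sweep a scenario list and collect one KPI table
#'
#' @inheritParams compare_scenarios
#' @param out_dir Optional directory; when given, writes `kpi.csv` (one row
#'   per scenario x replication plus aggregate rows).
#' @return Data frame of per-replication KPI rows across scenarios.
#' @export
run_scenario_sweep <- function(instance, scenarios = default_scenarios(),
                               n_reps = 30, base_seed = 1, out_dir = NULL,
                               ...) {
  rows <- list()
  for (s in scenarios) {
    run <- run_two_stage(instance, s, n_reps = n_reps, base_seed = base_seed,
                         ...)
    rep_rows <- cbind(scenario = s$id, model = s$model_id,
                      fleet_size = sum(s$fleet), run$reports)
    rows[[length(rows) + 1L]] <- rep_rows
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.csv(out, file.path(out_dir, "kpi.csv"), row.names = FALSE)
  }
  out
}

#' Write a route plan as JSON (and optionally GeoJSON)
#'
#' @param plan A `cc_route_plan`.
#' @param path Output JSON path.
#' @param instance Optional instance; when given, a sibling `.geojson` file
#'   with one LineString per route (depot-stops-depot) is written too.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path, instance = NULL) {
  obj <- list(
    optimality_tag = plan$optimality_tag,
    objective_nok_km = plan$objective_nok_km,
    routes = lapply(plan$routes, function(r) {
      list(vehicle_type = r$vehicle_type, stops = r$stops,
           length_km = r$length_km)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  if (!is.null(instance)) {
    loc <- instance$locations
    feats <- lapply(seq_along(plan$routes), function(i) {
      r <- plan$routes[[i]]
      ids <- c(0L, r$stops, 0L)
      coords <- lapply(ids, function(id) {
        c(loc$lon[loc$id == id], loc$lat[loc$id == id])
      })
      list(type = "Feature",
           properties = list(route = i, vehicle_type = r$vehicle_type,
                             length_km = r$length_km),
           geometry = list(type = "LineString", coordinates = coords))
    })
    gj <- list(type = "FeatureCollection", features = feats)
    jsonlite::write_json(gj, sub("\\.json$", ".geojson", path),
                         auto_unbox = TRUE, digits = 8)
  }
  invisible(path)
}
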