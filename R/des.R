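#' Simulation configuration
#'
#' Operational parameters of the delivery stage. Times inside the simulator
#' are minutes since the horizon start (00:00 of the start date, which
#' anchors the weekly order epochs); durations are rounded to the nearest
#' second internally so event ordering is float-stable.
#'
#' @param start,end Horizon dates (defaults 2020-12-28 and 2021-03-15; the
#'   start must be the first order Monday or any date — epochs fall on the
#'   first Monday at/after it and weekly thereafter).
#' @param window Shipping window as minutes-of-day `c(start, end)`; default
#'   06:00-15:00. Departures are window-gated; tours in progress complete
#'   past the window.
#' @param ship_days ISO weekdays on which departures are allowed (1 = Monday;
#'   default Monday-Friday).
#' @param outbound,inbound Uniform(min, max) processing times in minutes at
#'   the DC and at each stop (defaults U(20,30) and U(10,20)). Collapse to a
#'   constant with equal endpoints.
#' @param turnaround Minutes between a vehicle's return and its next
#'   availability (default 30).
#' @param fleet Named integer vector, vehicles per type, e.g.
#'   `c("e-NV200" = 3, "NV200" = 2)`.
#' @return A list of class `cc_sim_config`.
#' @export
sim_config <- function(start = as.Date("2020-12-28"),
                       end = as.Date("2021-03-15"),
                       window = c(6 * 60, 15 * 60),
                       ship_days = 1:5,
                       outbound = c(20, 30), inbound = c(10, 20),
                       turnaround = 30,
                       fleet = c("e-NV200" = 3, "NV200" = 2,
                                 "VW Transporter" = 0)) {
  start <- as.Date(start); end <- as.Date(end)
  stopifnot(window[1] < window[2], end >= start, all(fleet >= 0),
            outbound[1] <= outbound[2], inbound[1] <= inbound[2])
  structure(list(start = start, end = end, window = window,
                 ship_days = as.integer(ship_days),
                 outbound = outbound, inbound = inbound,
                 turnaround = turnaround, fleet = fleet),
            class = "cc_sim_config")
}

iso_weekday <- function(date) as.integer(format(as.Date(date), "%u"))

#' Earliest admissible departure time at or after `t`
#'
#' @param t Time in minutes since horizon start.
#' @param config A [sim_config()]; its `start` date fixes the weekday of
#'   minute 0 and `window`/`ship_days` the calendar.
#' @return Earliest in-window minute `>= t`. The window is closed-left,
#'   open-right: a departure exactly at window close rolls to the next
#'   shipping day.
#' @export
next_shipping_time <- function(t, config = sim_config()) {
  dow0 <- iso_weekday(config$start)
  ws <- config$window[1]; we <- config$window[2]
  day <- floor(t / 1440)
  tod <- t - day * 1440
  for (k in 0:8) {
    d <- day + k
    dow <- ((d + dow0 - 1) %% 7) + 1
    if (!(dow %in% config$ship_days)) next
    cand_tod <- if (k == 0) max(tod, ws) else ws
    if (cand_tod < we) return(d * 1440 + cand_tod)
  }
  stop("no shipping day within a week of t; check ship_days", call. = FALSE)
}

#' Sample from a triangular distribution by inverse CDF
#'
#' @param n Number of draws.
#' @param tmin,tmode,tmax Distribution parameters, `tmin <= tmode <= tmax`.
#' @return Numeric vector of draws in `[tmin, tmax]`.
#' @export
sample_triangular <- function(n, tmin, tmode, tmax) {
  stopifnot(tmin <= tmode, tmode <= tmax)
  if (tmax == tmin) return(rep(tmin, n))
  u <- runif(n)
  fc <- (tmode - tmin) / (tmax - tmin)
  ifelse(u < fc,
         tmin + sqrt(u * (tmax - tmin) * (tmode - tmin)),
         tmax - sqrt((1 - u) * (tmax - tmin) * (tmax - tmode)))
}

# round a duration to the nearest second (times are in minutes)
rsec <- function(x) round(x * 60) / 60

# Allocate `load` doses over per-stop backlogs proportionally with
# largest-remainder rounding; remainder ties go to the smaller center id.
split_load <- function(load, backlog, center_ids) {
  if (load >= sum(backlog)) return(backlog)
  share <- load * backlog / sum(backlog)
  out <- floor(share)
  left <- load - sum(out)
  if (left > 0) {
    ord <- order(-(share - out), center_ids)
    out[ord[seq_len(left)]] <- out[ord[seq_len(left)]] + 1
  }
  out
}

#' Execute one replication of a route plan
#'
#' Event-driven execution over the horizon: every order Monday 00:00 the
#' week's demands join the (total-backorder) backlog of their route; each
#' trip runs one planned route, departing less-than-truckload at the
#' earliest in-window instant when a vehicle of its type is idle; departure
#' is followed by one outbound-processing draw, each leg by a fresh
#' triangular speed draw, and each stop by an inbound-processing draw after
#' which that stop's doses are delivered (oldest order first). Routes whose
#' backlog exceeds the vehicle's dose capacity are repeated, loads split
#' proportionally across stops with largest-remainder rounding. Vehicles
#' turn idle `turnaround` minutes after return; no trip departs at or after
#' the horizon end instant (end date + 1 day, 00:00) — backlog never loaded
#' is reported as undelivered.
#'
#' Randomness is organised in per-route substreams keyed by `(seed, route)`,
#' each trip consuming a fixed-length draw block, so paired scenarios with a
#' common seed share identical route-level noise regardless of fleet size.
#'
#' @param instance A `cc_instance`.
#' @param plan A validated `cc_route_plan` covering every demanded center.
#' @param config A [sim_config()]; every vehicle type the plan uses needs a
#'   positive fleet count.
#' @param seed Integer replication seed.
#' @return A `cc_replication_log`: `shipments` (one row per delivered
#'   order-chunk), `trips`, `undelivered` doses per center, and `seed`.
#' @export
run_replication <- function(instance, plan, config = sim_config(), seed = 1) {
  loc <- instance$locations
  veh <- instance$vehicles
  d <- instance$distances
  n_routes <- length(plan$routes)
  types <- vapply(plan$routes, `[[`, character(1), "vehicle_type")
  bad <- setdiff(types, veh$name)
  if (length(bad)) {
    stop("plan references unknown vehicle type: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (ty in unique(types)) {
    if (is.na(config$fleet[ty]) || config$fleet[ty] < 1) {
      stop(sprintf("fleet has no vehicles of required type '%s'", ty),
           call. = FALSE)
    }
  }
  route_caps <- capacity_in_doses(veh[match(types, veh$name), ],
                                  instance$doses_per_m3)
  if (any(route_caps < 1)) {
    stop("a route's vehicle type has zero dose capacity; cannot ship",
         call. = FALSE)
  }
  route_legs_km <- lapply(plan$routes, function(r) route_legs(r$stops, d))
  speeds <- veh[match(types, veh$name), c("speed_min", "speed_mode", "speed_max")]

  center_route <- integer(0)
  for (r in seq_len(n_routes)) {
    center_route[as.character(plan$routes[[r]]$stops)] <- r
  }
  dem <- instance$demand[instance$demand$doses > 0, , drop = FALSE]
  no_route <- setdiff(unique(dem$center_id), as.integer(names(center_route)))
  if (length(no_route)) {
    stop("demanded center(s) missing from the plan: ",
         paste(no_route, collapse = ", "), call. = FALSE)
  }

  # per-route RNG substreams
  withr_seed(seed)
  route_seed <- sample.int(2147483646L, n_routes)
  rng_state <- vector("list", n_routes)
  draw <- function(r, fn) {
    if (is.null(rng_state[[r]])) set.seed(route_seed[r])
    else assign(".Random.seed", rng_state[[r]], envir = globalenv())
    out <- fn()
    rng_state[[r]] <<- get(".Random.seed", envir = globalenv())
    out
  }

  monday_off <- ((8L - iso_weekday(config$start)) %% 7L) * 1440
  weeks <- sort(unique(dem$week))
  etimes <- monday_off + weeks * 7 * 1440
  horizon_end <- (as.numeric(config$end - config$start) + 1) * 1440

  # backlog per route: parallel vectors center / order time / doses (FIFO)
  bl <- lapply(seq_len(n_routes), function(r) {
    list(center = integer(0), otime = numeric(0), doses = integer(0))
  })
  idle <- lapply(setNames(nm = unique(types)), function(ty) {
    rep(0, config$fleet[[ty]])
  })

  sh <- list(center = integer(0), doses = integer(0), otime = numeric(0),
             dtime = numeric(0))
  tr <- list(type = character(0), vindex = integer(0), route = integer(0),
             dep = numeric(0), ret = numeric(0), km = numeric(0),
             doses = integer(0))

  ep <- 1L
  repeat {
    has_bl <- vapply(bl, function(b) length(b$doses) > 0, logical(1))
    cand <- rep(Inf, n_routes)
    for (r in which(has_bl)) {
      t_avail <- min(idle[[types[r]]])
      cand[r] <- next_shipping_time(max(t_avail, min(bl[[r]]$otime)), config)
    }
    if (ep <= length(etimes) && (!any(has_bl) || min(cand) >= etimes[ep])) {
      rows <- dem[dem$week == weeks[ep], , drop = FALSE]
      rows <- rows[order(rows$center_id), , drop = FALSE]
      for (i in seq_len(nrow(rows))) {
        r <- center_route[[as.character(rows$center_id[i])]]
        bl[[r]]$center <- c(bl[[r]]$center, rows$center_id[i])
        bl[[r]]$otime <- c(bl[[r]]$otime, etimes[ep])
        bl[[r]]$doses <- c(bl[[r]]$doses, as.integer(rows$doses[i]))
      }
      ep <- ep + 1L
      next
    }
    if (!any(has_bl) || min(cand) >= horizon_end) break

    r <- which.min(cand)           # ties: lowest route index
    t0 <- cand[r]
    ty <- types[r]
    vi <- which.min(idle[[ty]])
    stops <- plan$routes[[r]]$stops
    ns <- length(stops)
    legs <- route_legs_km[[r]]

    b <- bl[[r]]
    per_stop <- vapply(stops, function(s) sum(b$doses[b$center == s]),
                       numeric(1))
    load <- min(sum(per_stop), route_caps[r])
    alloc <- split_load(load, per_stop, stops)

    blk <- draw(r, function() {
      list(out_min = runif(1, config$outbound[1], config$outbound[2]),
           speed = sample_triangular(ns + 1, speeds$speed_min[r],
                                     speeds$speed_mode[r], speeds$speed_max[r]),
           in_min = runif(ns, config$inbound[1], config$inbound[2]))
    })

    tcur <- t0 + rsec(blk$out_min)
    for (si in seq_len(ns)) {
      tcur <- tcur + rsec(legs[si] / blk$speed[si] * 60)
      tcur <- tcur + rsec(blk$in_min[si])
      take <- alloc[si]
      while (take > 0) {
        j <- which(b$center == stops[si])[1]   # FIFO: oldest chunk first
        got <- min(take, b$doses[j])
        sh$center <- c(sh$center, stops[si])
        sh$doses <- c(sh$doses, as.integer(got))
        sh$otime <- c(sh$otime, b$otime[j])
        sh$dtime <- c(sh$dtime, tcur)
        b$doses[j] <- b$doses[j] - got
        take <- take - got
        if (b$doses[j] == 0) {
          b$center <- b$center[-j]; b$otime <- b$otime[-j]
          b$doses <- b$doses[-j]
        }
      }
    }
    tcur <- tcur + rsec(legs[ns + 1] / blk$speed[ns + 1] * 60)
    bl[[r]] <- b
    idle[[ty]][vi] <- tcur + config$turnaround
    tr$type <- c(tr$type, ty); tr$vindex <- c(tr$vindex, vi)
    tr$route <- c(tr$route, r); tr$dep <- c(tr$dep, t0)
    tr$ret <- c(tr$ret, tcur)
    tr$km <- c(tr$km, plan$routes[[r]]$length_km)
    tr$doses <- c(tr$doses, as.integer(load))
  }

  grp <- setNames(loc$group, loc$id)
  shipments <- data.frame(center_id = sh$center, doses = sh$doses,
                          order_time_min = sh$otime,
                          delivery_time_min = sh$dtime)
  shipments$lead_time_days <- (shipments$delivery_time_min -
                                 shipments$order_time_min) / 1440
  shipments$group <- as.integer(grp[as.character(shipments$center_id)])
  elt <- instance$elt_days
  shipments$on_time <- shipments$lead_time_days <=
    as.numeric(elt[as.character(shipments$group)]) + 1e-12
  trips <- data.frame(vehicle_type = tr$type, vehicle_index = tr$vindex,
                      route = tr$route,
                      stops = vapply(tr$route, function(r) {
                        paste(plan$routes[[r]]$stops, collapse = ";")
                      }, character(1)),
                      departure_min = tr$dep, return_min = tr$ret,
                      distance_km = tr$km, doses_carried = tr$doses)
  demanded <- tapply(dem$doses, dem$center_id, sum)
  shipped <- tapply(shipments$doses, shipments$center_id, sum)
  cen_ids <- sort(unique(dem$center_id))
  undelivered <- data.frame(
    center_id = cen_ids,
    doses = as.integer(demanded[as.character(cen_ids)]) -
      ifelse(is.na(shipped[as.character(cen_ids)]), 0L,
             as.integer(shipped[as.character(cen_ids)]))
  )
  structure(list(shipments = shipments, trips = trips,
                 undelivered = undelivered, seed = seed,
                 horizon_end_min = horizon_end, start = config$start),
            class = "cc_replication_log")
}

#' @export
print.cc_replication_log <- function(x, ...) {
  cat(sprintf("<cc_replication_log> seed %s: %d shipments (%d doses), %d trips, %d doses undelivered\n",
              format(x$seed), nrow(x$shipments), sum(x$shipments$doses),
              nrow(x$trips), sum(x$undelivered$doses)))
  invisible(x)
}

#' Write a replication log as CSV with ISO timestamps
#'
#' Emits `shipments.csv` and `trips.csv` under `dir`.
#'
#' @param log A `cc_replication_log`.
#' @param dir Output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_replication <- function(log, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  t0 <- as.POSIXct(paste(log$start, "00:00:00"), tz = "UTC")
  iso <- function(m) format(t0 + round(m * 60), "%Y-%m-%dT%H:%M:%S")
  sh <- log$shipments
  sh$order_time <- iso(sh$order_time_min)
  sh$delivery_time <- iso(sh$delivery_time_min)
  write.csv(sh, file.path(dir, "shipments.csv"), row.names = FALSE)
  trp <- log$trips
  trp$departure <- iso(trp$departure_min)
  trp$return <- iso(trp$return_min)
  write.csv(trp, file.path(dir, "trips.csv"), row.names = FALSE)
  invisible(dir)
}
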