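#' Expected-lead-time service level
#'
#' Ratio of on-time deliveries to everything shipped. Dose-weighted by
#' default ("products" read as doses); `weighting = "shipment"` counts each
#' delivered order-chunk once. An empty log yields 1 by convention (no late
#' delivery occurred) with a warning.
#'
#' @param log A `cc_replication_log`.
#' @param elt_days Optional named ELT map (days per group) overriding the
#'   on-time flags recorded in the log.
#' @param weighting `"dose"` or `"shipment"`.
#' @return Fraction in `[0, 1]`.
#' @export
service_level <- function(log, elt_days = NULL,
                          weighting = c("dose", "shipment")) {
  weighting <- match.arg(weighting)
  sh <- log$shipments
  if (nrow(sh) == 0) {
    warning("no shipments in log; service level defined as 1")
    return(1)
  }
  on_time <- if (is.null(elt_days)) sh$on_time else {
    sh$lead_time_days <= as.numeric(elt_days[as.character(sh$group)]) + 1e-12
  }
  w <- if (weighting == "dose") sh$doses else rep(1, nrow(sh))
  sum(w * on_time) / sum(w)
}

#' Lead-time mean and maximum
#'
#' @inheritParams service_level
#' @return Named numeric `c(mean_days, max_days)`; the mean is dose-weighted
#'   by default.
#' @export
lead_time_stats <- function(log, weighting = c("dose", "shipment")) {
  weighting <- match.arg(weighting)
  sh <- log$shipments
  if (nrow(sh) == 0) stop("lead time undefined on an empty log", call. = FALSE)
  w <- if (weighting == "dose") sh$doses else rep(1, nrow(sh))
  c(mean_days = sum(w * sh$lead_time_days) / sum(w),
    max_days = max(sh$lead_time_days))
}

#' Transportation cost of a trip log
#'
#' Distance-based-with-fixed-cost policy: each trip costs its vehicle type's
#' per-km rate times the trip distance plus the fixed dispatch cost, counted
#' once per trip by default or once per stop under the per-stop basis.
#'
#' @param trips Trip data frame (`vehicle_type`, `distance_km`, `stops`).
#' @param catalogue Vehicle catalogue.
#' @param fixed_cost_basis `"per_trip"` or `"per_stop"`.
#' @return Total cost in NOK.
#' @export
transport_cost <- function(trips, catalogue = default_vehicles(),
                           fixed_cost_basis = c("per_trip", "per_stop")) {
  fixed_cost_basis <- match.arg(fixed_cost_basis)
  if (nrow(trips) == 0) return(0)
  k <- match(trips$vehicle_type, catalogue$name)
  if (anyNA(k)) {
    stop("unknown vehicle type in trips: ",
         paste(unique(trips$vehicle_type[is.na(k)]), collapse = ", "),
         call. = FALSE)
  }
  fixed_units <- if (fixed_cost_basis == "per_trip") 1 else {
    lengths(strsplit(as.character(trips$stops), ";"))
  }
  sum(catalogue$fixed_cost[k] * fixed_units +
        catalogue$var_cost_per_km[k] * trips$distance_km)
}

#' Tank-to-wheel CO2 emissions of a trip log
#'
#' @inheritParams transport_cost
#' @return Total grams of CO2 (battery-electric types contribute 0).
#' @export
co2_emissions <- function(trips, catalogue = default_vehicles()) {
  if (nrow(trips) == 0) return(0)
  k <- match(trips$vehicle_type, catalogue$name)
  if (anyNA(k)) {
    stop("unknown vehicle type in trips: ",
         paste(unique(trips$vehicle_type[is.na(k)]), collapse = ", "),
         call. = FALSE)
  }
  sum(catalogue$emission_g_per_km[k] * trips$distance_km)
}

#' One-row KPI report for a replication
#'
#' @param log A `cc_replication_log`.
#' @param instance The instance (for the vehicle catalogue).
#' @param fixed_cost_basis Passed to [transport_cost()].
#' @param weighting Passed to [service_level()] and [lead_time_stats()].
#' @return Data frame with `service_level`, `lead_mean_days`,
#'   `lead_max_days`, `cost_nok`, `co2_g`, `n_trips`, `undelivered_doses`,
#'   `seed`.
#' @export
kpi_report <- function(log, instance, fixed_cost_basis = "per_trip",
                       weighting = "dose") {
  lt <- if (nrow(log$shipments)) lead_time_stats(log, weighting) else
    c(mean_days = NA_real_, max_days = NA_real_)
  data.frame(
    service_level = suppressWarnings(service_level(log, weighting = weighting)),
    lead_mean_days = unname(lt["mean_days"]),
    lead_max_days = unname(lt["max_days"]),
    cost_nok = transport_cost(log$trips, instance$vehicles, fixed_cost_basis),
    co2_g = co2_emissions(log$trips, instance$vehicles),
    n_trips = nrow(log$trips),
    undelivered_doses = sum(log$undelivered$doses),
    seed = log$seed
  )
}

#' Monte-Carlo summary of per-replication KPI reports
#'
#' Per-KPI mean, standard deviation and two-sided Student-t confidence
#' half-width over the replications.
#'
#' @param reports Data frame of per-replication KPI rows ([kpi_report()]
#'   rows bound together), or a list of such rows.
#' @param confidence Two-sided confidence level (default 0.95).
#' @return Data frame with one row per KPI: `kpi`, `mean`, `sd`,
#'   `half_width`, `n`.
#' @export
aggregate_replications <- function(reports, confidence = 0.95) {
  if (is.list(reports) && !is.data.frame(reports)) {
    reports <- do.call(rbind, reports)
  }
  n <- nrow(reports)
  if (n < 2) stop("need at least 2 replications to aggregate", call. = FALSE)
  cols <- setdiff(names(reports), c("seed", "rep"))
  cols <- cols[vapply(reports[cols], is.numeric, logical(1))]
  tq <- qt(1 - (1 - confidence) / 2, df = n - 1)
  out <- do.call(rbind, lapply(cols, function(cn) {
    x <- reports[[cn]]
    s <- sd(x)
    data.frame(kpi = cn, mean = mean(x), sd = s,
               half_width = tq * s / sqrt(n), n = n)
  }))
  rownames(out) <- NULL
  out
}

#' Replication-batch stability test
#'
#' Runs `n_batches` independent batches of `n_per_batch` replications with
#' disjoint seed streams and reports the maximum relative spread of the
#' batch means across the headline KPIs. The scenario passes when the spread
#' stays below `tolerance`, i.e. results are driven by the model and not by
#' the draw of the stochastic scenario tree.
#'
#' @param instance A `cc_instance`.
#' @param scen A [scenario()].
#' @param n_per_batch,n_batches Batch sizing (defaults 30 and 2).
#' @param tolerance Maximum admissible relative spread (default 0.05).
#' @param base_seed Base seed; batch `b` uses the derived stream
#'   `derive_seed(base_seed, scenario, b * n_per_batch + r)`.
#' @return List: `pass`, `spread`, `batch_means` (batches x KPIs matrix).
#' @export
stability_check <- function(instance, scen, n_per_batch = 30, n_batches = 2,
                            tolerance = 0.05, base_seed = 1) {
  stopifnot(n_batches >= 2)
  kpis <- c("service_level", "lead_mean_days", "cost_nok", "co2_g")
  staged <- stage_scenario(instance, scen)
  means <- matrix(NA_real_, n_batches, length(kpis),
                  dimnames = list(NULL, kpis))
  for (b in seq_len(n_batches)) {
    reps <- lapply(seq_len(n_per_batch), function(r) {
      s <- derive_seed(base_seed, scen$id, (b - 1) * n_per_batch + r)
      kpi_report(run_replication(staged$instance, staged$plan, staged$config,
                                 seed = s), staged$instance)
    })
    reps <- do.call(rbind, reps)
    means[b, ] <- vapply(kpis, function(k) mean(reps[[k]]), numeric(1))
  }
  spread <- max(vapply(seq_along(kpis), function(j) {
    m <- means[, j]
    if (max(m) == min(m)) return(0)
    (max(m) - min(m)) / abs(mean(m))
  }, numeric(1)))
  list(pass = spread < tolerance, spread = spread, batch_means = means)
}
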