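#' Configuration for the synthetic-instance generator
#'
#' The generator emulates the statistical shape of a Norwegian-county-like
#' study region: 46 municipal vaccination centers, an adult (18+) population
#' of 301,975 split heavy-tailed across municipalities, a handful of
#' high-infection municipalities receiving a 20% dose uplift, and a
#' supply-driven weekly dose schedule over 12 order epochs.
#'
#' @param n_centers Number of vaccination centers (default 46).
#' @param total_population_18plus Total adult population (default 301975).
#' @param concentration Gamma shape for the Dirichlet-like population split;
#'   smaller = more unequal municipality sizes (default 0.8).
#' @param n_high_infection Number of flagged high-infection centers; the `n`
#'   most populous are flagged (default 5).
#' @param uplift_fraction Dose uplift for flagged centers (default 0.20).
#' @param weekly_base Week-0 county-wide dose supply (default 4000).
#' @param weekly_growth Weekly multiplicative supply growth (default 0.05).
#' @param n_weeks Number of weekly order epochs (default 12).
#' @param sigma Lognormal sigma applied multiplicatively to the weekly total
#'   and to per-center shares (default 0.25; 0 = deterministic).
#' @param bbox Coordinate bounding box `c(lat_min, lat_max, lon_min, lon_max)`.
#' @param depot_lat,depot_lon Depot coordinates (default Oslo).
#' @param circuity Road circuity factor passed through to the instance.
#' @return A list of class `cc_synth_config`.
#' @export
synth_config <- function(n_centers = 46, total_population_18plus = 301975,
                         concentration = 0.8, n_high_infection = 5,
                         uplift_fraction = 0.20,
                         weekly_base = 4000, weekly_growth = 0.05,
                         n_weeks = 12, sigma = 0.25,
                         bbox = c(60.0, 62.7, 9.5, 12.5),
                         depot_lat = 59.913, depot_lon = 10.752,
                         circuity = 1.3) {
  stopifnot(n_high_infection <= n_centers, uplift_fraction >= 0, sigma >= 0,
            n_centers >= 1, n_weeks >= 1, concentration > 0)
  if (bbox[2] < bbox[1] || bbox[4] < bbox[3]) {
    stop("degenerate bounding box", call. = FALSE)
  }
  structure(as.list(environment()), class = "cc_synth_config")
}

#' Largest-remainder rounding preserving an integer total
#'
#' Rounds non-negative shares to integers summing exactly to `total`: floor
#' everything, then hand the leftover units to the largest fractional
#' remainders (ties broken by position).
#'
#' @param x Non-negative numeric shares (any scale).
#' @param total Integer total to conserve.
#' @return Integer vector summing to `total`.
#' @export
largest_remainder <- function(x, total) {
  total <- as.integer(round(total))
  if (total == 0 || all(x == 0)) return(integer(length(x)) + 0L)
  share <- x / sum(x) * total
  out <- floor(share)
  left <- total - sum(out)
  if (left > 0) {
    ord <- order(share - out, decreasing = TRUE)
    out[ord[seq_len(left)]] <- out[ord[seq_len(left)]] + 1
  }
  as.integer(out)
}

#' Generate depot plus center locations
#'
#' Centers are placed uniformly in the bounding box; populations follow a
#' normalised gamma (Dirichlet-like) split scaled to the configured total with
#' largest-remainder rounding; the `n_high_infection` most populous centers
#' are flagged. Deterministic given the seed.
#'
#' @param cfg A [synth_config()].
#' @param seed Integer RNG seed.
#' @return A location table (depot node 0 first); `group` is NA until
#'   [assign_customer_groups()] is applied.
#' @export
generate_locations <- function(cfg = synth_config(), seed = 1) {
  withr_seed(seed)
  n <- cfg$n_centers
  lat <- runif(n, cfg$bbox[1], cfg$bbox[2])
  lon <- runif(n, cfg$bbox[3], cfg$bbox[4])
  w <- stats::rgamma(n, shape = cfg$concentration, rate = 1)
  pop <- largest_remainder(w, cfg$total_population_18plus)
  flagged <- rep(FALSE, n)
  if (cfg$n_high_infection > 0) {
    flagged[order(pop, decreasing = TRUE)[seq_len(cfg$n_high_infection)]] <- TRUE
  }
  make_locations(
    id = 0:n,
    name = c("DC", sprintf("center_%02d", 1:n)),
    lat = c(cfg$depot_lat, lat), lon = c(cfg$depot_lon, lon),
    role = c("depot", rep("center", n)),
    population_18plus = c(0, pop),
    high_infection = c(FALSE, flagged),
    group = rep(NA_integer_, n + 1)
  )
}

# Seed scoping: set the RNG seed and restore the caller's state on exit.
withr_seed <- function(seed) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    do.call(on.exit,
            list(bquote(assign(".Random.seed", .(old), envir = globalenv())),
                 add = TRUE),
            envir = parent.frame())
  }
  set.seed(as.integer(seed %% 2147483647))
  invisible(NULL)
}

#' Generate a weekly demand series
#'
#' Week `w`'s county-wide supply is `weekly_base * (1+weekly_growth)^w` times
#' a lognormal(0, sigma) draw. It is allocated to centers proportionally to
#' `population_18plus * (1 + uplift * high_infection)` times per-center
#' lognormal(0, sigma) share noise, with largest-remainder rounding so each
#' week's total is conserved exactly.
#'
#' @param cfg A [synth_config()].
#' @param locations Output of [generate_locations()].
#' @param seed Integer RNG seed.
#' @return Demand data frame (`week`, `center_id`, `doses`) with attributes
#'   `weekly_totals` (realised totals) and `noise` (weeks x centers share
#'   multipliers).
#' @export
generate_demand <- function(cfg = synth_config(), locations, seed = 1) {
  withr_seed(seed)
  cen <- locations[locations$role == "center", , drop = FALSE]
  n <- nrow(cen)
  weight <- cen$population_18plus *
    (1 + cfg$uplift_fraction * as.numeric(cen$high_infection))
  totals <- numeric(cfg$n_weeks)
  noise <- matrix(NA_real_, cfg$n_weeks, n)
  doses <- matrix(0L, cfg$n_weeks, n)
  for (w in seq_len(cfg$n_weeks)) {
    tot_noise <- if (cfg$sigma > 0) stats::rlnorm(1, 0, cfg$sigma) else 1
    total_w <- as.integer(round(cfg$weekly_base *
                                  (1 + cfg$weekly_growth)^(w - 1) * tot_noise))
    mult <- if (cfg$sigma > 0) stats::rlnorm(n, 0, cfg$sigma) else rep(1, n)
    totals[w] <- total_w
    noise[w, ] <- mult
    doses[w, ] <- largest_remainder(weight * mult, total_w)
  }
  dem <- data.frame(
    week = rep(seq_len(cfg$n_weeks) - 1L, each = n),
    center_id = rep(cen$id, cfg$n_weeks),
    doses = as.integer(t(doses))
  )
  attr(dem, "weekly_totals") <- totals
  attr(dem, "noise") <- noise
  dem
}

#' Partition centers into two customer groups by proximity to the DC
#'
#' Group 1 is the near set (tight expected lead time), group 2 the far set.
#' The default threshold is the median great-circle distance to the DC, so
#' the groups are (near-)balanced.
#'
#' @param locations Location table.
#' @param dc Optional `c(lat, lon)` of the DC; defaults to the depot row.
#' @param threshold `"median"` or a numeric distance in km.
#' @return Integer group labels (1 or 2) for every center, in location-table
#'   order with NA at the depot row.
#' @export
assign_customer_groups <- function(locations, dc = NULL,
                                   threshold = "median") {
  if (is.null(dc)) {
    dep <- locations[locations$role == "depot", ]
    dc <- c(dep$lat, dep$lon)
  }
  is_cen <- locations$role == "center"
  d <- haversine_km(dc[1], dc[2], locations$lat[is_cen], locations$lon[is_cen])
  thr <- if (identical(threshold, "median")) median(d) else as.numeric(threshold)
  g <- rep(NA_integer_, nrow(locations))
  g[is_cen] <- ifelse(d <= thr, 1L, 2L)
  g
}

#' Vehicle catalogue used in the case experiments
#'
#' Three small refrigerated-van types: a battery-electric Nissan e-NV200
#' (2.1 m3 cooling cube, 300 km range, zero tank-to-wheel emissions,
#' 6 NOK/km), a Nissan NV200 (2.1 m3, 1000 km, 131 g CO2/km, 8 NOK/km) and a
#' VW Transporter (6.7 m3, 1000 km, 159 g/km, 10 NOK/km); all with a 1500 NOK
#' fixed dispatch cost and triangular(40, 50, 70) km/h speed.
#'
#' @return Vehicle-catalogue data frame.
#' @export
default_vehicles <- function() {
  veh <- data.frame(
    name = c("e-NV200", "NV200", "VW Transporter"),
    capacity_m3 = c(2.1, 2.1, 6.7),
    range_km = c(300, 1000, 1000),
    speed_min = 40, speed_mode = 50, speed_max = 70,
    var_cost_per_km = c(6, 8, 10),
    fixed_cost = 1500,
    emission_g_per_km = c(0, 131, 159),
    stringsAsFactors = FALSE
  )
  validate_vehicles(veh)
}

#' The ten benchmark scenarios
#'
#' Fleet-size/composition ladder over the three network models: Model 1
#' (depot at the Oslo-like corner, mixed EV + combustion fleet), Model 2
#' (relocated central DC, same fleet types, 1-day ELT for both groups),
#' Model 3 (Oslo-like depot, combustion-only NV200 + VW Transporter fleet).
#'
#' @return A list of `cc_scenario` objects (see [scenario()]).
#' @export
default_scenarios <- function() {
  spec <- list(
    list(1, 1, c("e-NV200" = 1, "NV200" = 2)),
    list(2, 1, c("e-NV200" = 3, "NV200" = 2)),
    list(3, 1, c("e-NV200" = 4, "NV200" = 2)),
    list(4, 2, c("e-NV200" = 1, "NV200" = 2)),
    list(5, 2, c("e-NV200" = 3, "NV200" = 2)),
    list(6, 2, c("e-NV200" = 4, "NV200" = 2)),
    list(7, 2, c("e-NV200" = 4, "NV200" = 3)),
    list(8, 3, c("NV200" = 1, "VW Transporter" = 2)),
    list(9, 3, c("NV200" = 2, "VW Transporter" = 3)),
    list(10, 3, c("NV200" = 3, "VW Transporter" = 3))
  )
  lapply(spec, function(s) scenario(id = s[[1]], model_id = s[[2]],
                                    fleet = s[[3]]))
}

#' Generate a complete synthetic instance
#'
#' Convenience wrapper: locations, customer groups relative to the depot,
#' demand series, default vehicle catalogue and ELT map assembled into a
#' validated instance. Fully reproducible from `(cfg, seed)`.
#'
#' @param cfg A [synth_config()].
#' @param seed Integer RNG seed.
#' @return A `cc_instance`.
#' @export
synthetic_instance <- function(cfg = synth_config(), seed = 1) {
  loc <- generate_locations(cfg, seed = seed)
  loc$group <- assign_customer_groups(loc)
  dem <- generate_demand(cfg, loc, seed = seed + 1)
  start <- as.Date("2020-12-28")
  make_instance(loc, dem, default_vehicles(),
                elt_days = c("1" = 1, "2" = 2),
                horizon = c(start, start + 7 * (cfg$n_weeks - 1)),
                doses_per_m3 = 600, circuity = cfg$circuity)
}
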