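#' @useDynLib coldchainr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median qt rnorm runif sd setNames
#' @importFrom utils read.csv write.csv head
NULL

EARTH_RADIUS_KM <- 6371

#' Great-circle distance between points on the WGS84 reference sphere
#'
#' Haversine formula on a sphere of radius 6371 km. Vectorised over all four
#' coordinate arguments (recycled as usual).
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in kilometers.
#' @examples
#' haversine_km(59.913, 10.752, 60.794, 11.068) # Oslo - Hamar, ~ 99.7 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad
  phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)) ||
      any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180)) {
    stop("invalid coordinates: lat must lie in [-90, 90], lon in [-180, 180]",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Road-approximating distance matrix
#'
#' Builds the symmetric node-to-node distance matrix used by both the route
#' optimizer and the simulator. Real road distances are unavailable offline,
#' so road length is approximated as great-circle distance times a circuity
#' factor; the construction is recorded in the `metric_tag` attribute.
#'
#' @param locations Location table (see [make_locations()]); row order gives
#'   node indices, depot first.
#' @param circuity Dimensionless road circuity factor, must be >= 1.
#' @return A `|V| x |V|` numeric matrix of km with zero diagonal and a
#'   `metric_tag` attribute.
#' @export
build_distance_matrix <- function(locations, circuity = 1.3) {
  if (!is.numeric(circuity) || length(circuity) != 1 || !is.finite(circuity) ||
      circuity < 1) {
    stop("circuity must be a single number >= 1", call. = FALSE)
  }
  lat <- locations$lat
  lon <- locations$lon
  n <- length(lat)
  d <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      dij <- haversine_km(lat[i], lon[i], lat[j], lon[j]) * circuity
      d[i, j] <- dij
      d[j, i] <- dij
    }
  }
  dimnames(d) <- list(locations$id, locations$id)
  attr(d, "metric_tag") <- sprintf("haversine_km*circuity=%g", circuity)
  d
}

#' Convert vehicle cargo volume to a dose capacity
#'
#' @param vehicles A vehicle-catalogue data frame (or a single row of one)
#'   with a `capacity_m3` column, or a bare numeric vector of cubic meters.
#' @param doses_per_m3 Packing density, doses per cubic meter (default 600).
#' @return Integer dose capacity, `floor(capacity_m3 * doses_per_m3)`.
#' @export
capacity_in_doses <- function(vehicles, doses_per_m3 = 600) {
  if (!is.numeric(doses_per_m3) || doses_per_m3 <= 0) {
    stop("doses_per_m3 must be > 0", call. = FALSE)
  }
  m3 <- if (is.data.frame(vehicles)) vehicles$capacity_m3 else vehicles
  if (any(m3 < 0)) stop("capacity_m3 must be >= 0", call. = FALSE)
  as.integer(floor(m3 * doses_per_m3))
}

#' Construct and validate a location table
#'
#' Nodes of the distribution network: exactly one depot (node id 0) and the
#' vaccination centers (ids 1..n). `group` is the customer-group id (1 = near
#' the DC with a tight expected lead time, 2 = far) and is NA for the depot.
#'
#' @param id,name,lat,lon,role,population_18plus,high_infection,group Column
#'   vectors; see the locations.csv interface.
#' @return A validated `data.frame`.
#' @export
make_locations <- function(id, name, lat, lon, role, population_18plus,
                           high_infection, group) {
  loc <- data.frame(
    id = as.integer(id), name = as.character(name),
    lat = as.numeric(lat), lon = as.numeric(lon),
    role = as.character(role),
    population_18plus = as.numeric(population_18plus),
    high_infection = as.logical(high_infection),
    group = suppressWarnings(as.integer(group)),
    stringsAsFactors = FALSE
  )
  validate_locations(loc)
  loc
}

validate_locations <- function(loc) {
  if (anyDuplicated(loc$id)) stop("location ids must be unique", call. = FALSE)
  if (!identical(sort(loc$id), seq_len(nrow(loc)) - 1L)) {
    stop("location ids must be contiguous integers starting at 0",
         call. = FALSE)
  }
  n_dep <- sum(loc$role == "depot")
  if (n_dep != 1L) {
    stop(sprintf("exactly one depot required, found %d", n_dep), call. = FALSE)
  }
  if (loc$id[loc$role == "depot"] != 0L) {
    stop("the depot must be node 0", call. = FALSE)
  }
  if (!all(loc$role %in% c("depot", "center"))) {
    stop("role must be 'depot' or 'center'", call. = FALSE)
  }
  check_coords(loc$lat, loc$lon)
  if (any(loc$population_18plus < 0)) {
    stop("population_18plus must be >= 0", call. = FALSE)
  }
  invisible(loc)
}

validate_vehicles <- function(veh) {
  need <- c("name", "capacity_m3", "range_km", "speed_min", "speed_mode",
            "speed_max", "var_cost_per_km", "fixed_cost", "emission_g_per_km")
  miss <- setdiff(need, names(veh))
  if (length(miss)) {
    stop("vehicle catalogue missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  num <- veh[setdiff(need, "name")]
  if (any(vapply(num, function(x) any(x < 0), logical(1)))) {
    stop("vehicle magnitudes must be >= 0", call. = FALSE)
  }
  bad <- veh$speed_min > veh$speed_mode | veh$speed_mode > veh$speed_max |
    veh$speed_min <= 0
  if (any(bad)) {
    stop("vehicle speed must satisfy 0 < min <= mode <= max (row ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  }
  if (anyDuplicated(veh$name)) {
    stop("vehicle type names must be unique", call. = FALSE)
  }
  invisible(veh)
}

validate_demand <- function(dem, loc, n_weeks = NULL) {
  centers <- loc$id[loc$role == "center"]
  bad <- setdiff(unique(dem$center_id), centers)
  if (length(bad)) {
    stop("demand references unknown center id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(dem$doses < 0)) {
    i <- which(dem$doses < 0)[1]
    stop(sprintf("negative doses in demand row %d (week %d, center %d)",
                 i, dem$week[i], dem$center_id[i]), call. = FALSE)
  }
  if (anyDuplicated(dem[c("week", "center_id")])) {
    stop("at most one demand entry per (week, center)", call. = FALSE)
  }
  if (any(dem$week < 0)) stop("week indices must be >= 0", call. = FALSE)
  if (!is.null(n_weeks) && any(dem$week >= n_weeks)) {
    stop("demand week index outside the planning horizon", call. = FALSE)
  }
  invisible(dem)
}

#' Assemble a distribution instance
#'
#' Bundles locations, weekly demand, vehicle catalogue, expected-lead-time map
#' and horizon into a validated `cc_instance`, computing the distance matrix.
#'
#' @param locations Location table (depot = node 0).
#' @param demand Data frame `week` (0-based), `center_id`, `doses`.
#' @param vehicles Vehicle catalogue, see [default_vehicles()].
#' @param elt_days Named numeric, expected lead time in days per customer
#'   group, e.g. `c("1" = 1, "2" = 2)`.
#' @param horizon Length-2 `Date` vector (start, end); start anchors week 0.
#' @param doses_per_m3 Packing density (default 600 doses per cubic meter).
#' @param circuity Road circuity factor for the distance matrix.
#' @return An object of class `cc_instance`.
#' @export
make_instance <- function(locations, demand, vehicles,
                          elt_days = c("1" = 1, "2" = 2),
                          horizon = as.Date(c("2020-12-28", "2021-03-15")),
                          doses_per_m3 = 600, circuity = 1.3) {
  validate_locations(locations)
  validate_vehicles(vehicles)
  validate_demand(demand, locations)
  grp <- unique(locations$group[locations$role == "center"])
  grp <- grp[!is.na(grp)]
  miss <- setdiff(as.character(grp), names(elt_days))
  if (length(miss)) {
    stop("elt_days missing for group(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  horizon <- as.Date(horizon)
  if (length(horizon) != 2 || horizon[2] < horizon[1]) {
    stop("horizon must be (start, end) with end >= start", call. = FALSE)
  }
  inst <- structure(list(
    locations = locations,
    demand = demand[order(demand$week, demand$center_id), , drop = FALSE],
    vehicles = vehicles,
    distances = build_distance_matrix(locations, circuity),
    elt_days = elt_days,
    horizon = horizon,
    doses_per_m3 = doses_per_m3,
    circuity = circuity
  ), class = "cc_instance")
  rownames(inst$demand) <- NULL
  inst
}

#' @export
print.cc_instance <- function(x, ...) {
  nc <- sum(x$locations$role == "center")
  cat(sprintf("<cc_instance> %d centers + depot, %d demand rows over weeks %s, %d vehicle types\n",
              nc, nrow(x$demand),
              if (nrow(x$demand)) paste0(min(x$demand$week), "-", max(x$demand$week)) else "-",
              nrow(x$vehicles)))
  cat(sprintf("  horizon %s .. %s | %g doses/m3 | distances: %s\n",
              format(x$horizon[1]), format(x$horizon[2]), x$doses_per_m3,
              attr(x$distances, "metric_tag")))
  invisible(x)
}

#' Write an instance to a directory of plain-text files
#'
#' Emits `locations.csv`, `demand.csv`, `vehicles.csv` and `instance.json`
#' (horizon, ELT map, packing density, circuity, file references).
#'
#' @param instance A `cc_instance`.
#' @param dir Output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_instance <- function(instance, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(instance$locations, file.path(dir, "locations.csv"),
            row.names = FALSE)
  write.csv(instance$demand, file.path(dir, "demand.csv"), row.names = FALSE)
  write.csv(instance$vehicles, file.path(dir, "vehicles.csv"),
            row.names = FALSE)
  meta <- list(
    horizon = format(instance$horizon),
    elt_days = as.list(instance$elt_days),
    doses_per_m3 = instance$doses_per_m3,
    circuity = instance$circuity,
    files = list(locations = "locations.csv", demand = "demand.csv",
                 vehicles = "vehicles.csv")
  )
  jsonlite::write_json(meta, file.path(dir, "instance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read an instance written by [write_instance()]
#'
#' Validates every instance invariant; schema violations raise errors naming
#' the offending record.
#'
#' @param dir Directory containing `instance.json` and the referenced CSVs.
#' @return A `cc_instance`.
#' @export
read_instance <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "instance.json"),
                              simplifyVector = TRUE)
  loc <- read.csv(file.path(dir, meta$files$locations),
                  stringsAsFactors = FALSE)
  loc$group <- suppressWarnings(as.integer(loc$group))
  loc$high_infection <- as.logical(loc$high_infection)
  dem <- read.csv(file.path(dir, meta$files$demand))
  veh <- read.csv(file.path(dir, meta$files$vehicles),
                  stringsAsFactors = FALSE)
  make_instance(loc, dem, veh,
                elt_days = unlist(meta$elt_days),
                horizon = as.Date(meta$horizon),
                doses_per_m3 = meta$doses_per_m3,
                circuity = meta$circuity)
}
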