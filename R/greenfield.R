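#' Center-of-gravity (greenfield) facility location
#'
#' Weighted geometric median of the customer sites by Weiszfeld iteration on
#' locally projected planar coordinates (equirectangular about the weighted
#' centroid). Iterations stop when the move falls below `tol_m` meters. The
#' objective `sum(w_i * dist_i)` is non-increasing across iterations; the
#' trace is attached as attribute `objective_trace` (km-weighted).
#'
#' @param lat,lon Customer coordinates in decimal degrees.
#' @param weights Non-negative weights (e.g. dose volumes), not all zero.
#' @param tol_m Convergence tolerance on the move, meters (default 1).
#' @param max_iter Iteration cap.
#' @return `c(lat, lon)` of the sited facility.
#' @export
greenfield_location <- function(lat, lon, weights = rep(1, length(lat)),
                                tol_m = 1, max_iter = 1000L) {
  check_coords(lat, lon)
  if (length(lat) < 1) stop("at least one customer required", call. = FALSE)
  if (any(weights < 0) || all(weights == 0)) {
    stop("weights must be >= 0 and not all zero", call. = FALSE)
  }
  if (length(lat) == 1) return(c(lat = lat, lon = lon))
  deg_km <- EARTH_RADIUS_KM * pi / 180
  lat0 <- sum(weights * lat) / sum(weights)
  kx <- deg_km * cos(lat0 * pi / 180)
  x <- lon * kx
  y <- lat * deg_km
  px <- sum(weights * x) / sum(weights)
  py <- sum(weights * y) / sum(weights)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    di <- sqrt((x - px)^2 + (y - py)^2)
    trace <- c(trace, sum(weights * di))
    di <- pmax(di, 1e-9)
    wi <- weights / di
    nx <- sum(wi * x) / sum(wi)
    ny <- sum(wi * y) / sum(wi)
    move_km <- sqrt((nx - px)^2 + (ny - py)^2)
    px <- nx; py <- ny
    if (move_km < tol_m / 1000) break
  }
  out <- c(lat = py / deg_km, lon = px / kx)
  attr(out, "objective_trace") <- trace
  out
}

#' Customer-group to vehicle-type mapping for the three network models
#'
#' Models 1 and 2 serve the near group with the battery-electric e-NV200 and
#' the far group with the NV200; Model 3 is combustion-only, NV200 for the
#' near group and VW Transporter for the far group. An explicit override map
#' is returned verbatim after checking that the types exist.
#'
#' @param model_id 1, 2 or 3.
#' @param catalogue Vehicle catalogue (default [default_vehicles()]).
#' @param override Optional named character vector `c("1" = type, "2" = type)`.
#' @return Named character vector mapping group id to vehicle-type name.
#' @export
assign_vehicle_types <- function(model_id, catalogue = default_vehicles(),
                                 override = NULL) {
  if (!is.null(override)) {
    bad <- setdiff(override, catalogue$name)
    if (length(bad)) {
      stop("override references unknown vehicle type(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (!all(c("1", "2") %in% names(override))) {
      stop("override must name groups \"1\" and \"2\"", call. = FALSE)
    }
    return(override[c("1", "2")])
  }
  maps <- list(`1` = c("1" = "e-NV200", "2" = "NV200"),
               `2` = c("1" = "e-NV200", "2" = "NV200"),
               `3` = c("1" = "NV200", "2" = "VW Transporter"))
  key <- as.character(model_id)
  if (!key %in% names(maps)) {
    stop("unknown model_id: ", model_id, " (must be 1, 2 or 3)", call. = FALSE)
  }
  m <- maps[[key]]
  bad <- setdiff(m, catalogue$name)
  if (length(bad)) {
    stop("catalogue lacks type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m
}
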