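test_that("shipping calendar returns the earliest in-window departure", {
  cfg <- sim_config()          # start 2020-12-28, a Monday
  day <- function(d, hm) d * 1440 + hm[1] * 60 + hm[2]
  # Wednesday 10:00 is already in window
  expect_equal(next_shipping_time(day(2, c(10, 0)), cfg), day(2, c(10, 0)))
  # Friday 16:00 -> Monday 06:00
  expect_equal(next_shipping_time(day(4, c(16, 0)), cfg), day(7, c(6, 0)))
  # Monday 05:00 -> Monday 06:00
  expect_equal(next_shipping_time(day(0, c(5, 0)), cfg), day(0, c(6, 0)))
  # Saturday -> Monday 06:00
  expect_equal(next_shipping_time(day(5, c(9, 0)), cfg), day(7, c(6, 0)))
  # window close rolls over
  expect_equal(next_shipping_time(day(0, c(15, 0)), cfg), day(1, c(6, 0)))
})

test_that("triangular sampler respects support and is inverse-CDF reproducible", {
  set.seed(101)
  x <- sample_triangular(2000, 40, 50, 70)
  expect_true(all(x >= 40 & x <= 70))
  set.seed(101)
  expect_identical(x, sample_triangular(2000, 40, 50, 70))
  expect_equal(sample_triangular(5, 50, 50, 50), rep(50, 5))
})

test_that("deterministic single-route replication reproduces the hand trace", {
  inst <- mk_trace_instance(doses = 100)
  plan <- mk_plan(inst, 1)
  cfg <- deterministic_sim(fleet = c(NV200 = 1))
  log <- run_replication(inst, plan, cfg, seed = 1)
  # Monday 06:00 departure + 25 outbound + 120 travel + 15 inbound = 08:40
  expect_equal(log$trips$departure_min, 360)
  expect_equal(log$shipments$delivery_time_min, 360 + 25 + 120 + 15)
  expect_equal(log$shipments$lead_time_days, 520 / 1440)
  expect_equal(round(log$shipments$lead_time_days, 3), 0.361)
  expect_true(log$shipments$on_time)
  # return after the second 120-min leg
  expect_equal(log$trips$return_min, 520 + 120)
  expect_equal(log$trips$distance_km, 200)
  expect_equal(sum(log$undelivered$doses), 0)
})

test_that("capacity forces repeated trips and backlog merges across weeks", {
  # 2520 doses in one week on a 1260-capacity route -> exactly 2 trips
  inst <- mk_trace_instance(doses = 2520)
  plan <- mk_plan(inst, 1)
  log <- run_replication(inst, plan, deterministic_sim(c(NV200 = 1)),
                         seed = 2)
  expect_equal(nrow(log$trips), 2)
  expect_equal(log$trips$doses_carried, c(1260L, 1260L))
  expect_equal(sum(log$shipments$doses), 2520)
  expect_equal(sum(log$undelivered$doses), 0)

  # zero demand -> no events at all
  inst0 <- mk_trace_instance(doses = 0)
  log0 <- run_replication(inst0, plan, deterministic_sim(c(NV200 = 1)),
                          seed = 3)
  expect_equal(nrow(log0$trips), 0)
  expect_equal(nrow(log0$shipments), 0)
  expect_equal(sum(log0$undelivered$doses), 0)
})

test_that("replications are seed-deterministic and seeds matter", {
  inst <- synthetic_instance(synth_config(n_centers = 10), seed = 4)
  plan <- solve_cvrp(inst, cvrp_config(vehicle_types = "NV200"))
  cfg <- sim_config(fleet = c(NV200 = 2))
  a <- run_replication(inst, plan, cfg, seed = 11)
  b <- run_replication(inst, plan, cfg, seed = 11)
  expect_identical(a$shipments, b$shipments)
  expect_identical(a$trips, b$trips)
  c3 <- run_replication(inst, plan, cfg, seed = 12)
  expect_false(identical(a$shipments, c3$shipments))
})

test_that("simulation invariants: conservation, window gating, planned distances", {
  inst <- synthetic_instance(synth_config(n_centers = 12), seed = 6)
  plan <- solve_cvrp(inst, cvrp_config(vehicle_types = c("NV200")),
                     method = "exact")
  cfg <- sim_config(fleet = c(NV200 = 2))
  for (seed in 1:3) {
    log <- run_replication(inst, plan, cfg, seed = seed)
    # conservation per center
    dem <- tapply(inst$demand$doses, inst$demand$center_id, sum)
    shp <- tapply(log$shipments$doses, log$shipments$center_id, sum)
    for (id in names(dem)) {
      got <- if (id %in% names(shp)) shp[[id]] else 0
      und <- log$undelivered$doses[log$undelivered$center_id == as.integer(id)]
      expect_equal(got + und, dem[[id]])
    }
    # departures inside the shipping window, before the horizon end
    tod <- log$trips$departure_min %% 1440
    dow <- (floor(log$trips$departure_min / 1440) %% 7) + 1
    expect_true(all(tod >= 360 & tod < 900))
    expect_true(all(dow %in% 1:5))
    expect_true(all(log$trips$departure_min < log$horizon_end_min))
    # every trip distance equals its planned route length
    lens <- vapply(plan$routes, `[[`, numeric(1), "length_km")
    expect_equal(log$trips$distance_km, lens[log$trips$route])
    # lead times strictly positive, on-time flags consistent with the ELT map
    expect_true(all(log$shipments$lead_time_days > 0))
    elt <- inst$elt_days[as.character(log$shipments$group)]
    expect_equal(log$shipments$on_time,
                 log$shipments$lead_time_days <= as.numeric(elt) + 1e-12)
  }
})

test_that("replication errors name missing vehicle types", {
  inst <- mk_trace_instance()
  plan <- mk_plan(inst, 1)
  expect_error(run_replication(inst, plan, deterministic_sim(c(NV200 = 0)),
                               seed = 1),
               "no vehicles of required type 'NV200'")
  plan2 <- mk_plan(inst, 1, type = "hovercraft")
  expect_error(run_replication(inst, plan2, deterministic_sim(c(NV200 = 1)),
                               seed = 1),
               "unknown vehicle type")
})

test_that("replication logs round-trip to CSV with ISO timestamps", {
  inst <- mk_trace_instance(doses = 100)
  log <- run_replication(inst, mk_plan(inst, 1),
                         deterministic_sim(c(NV200 = 1)), seed = 1)
  dir <- tempfile("log")
  write_replication(log, dir)
  sh <- read.csv(file.path(dir, "shipments.csv"))
  expect_equal(sh$delivery_time, "2020-12-28T08:40:00")
  expect_true(file.exists(file.path(dir, "trips.csv")))
})
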