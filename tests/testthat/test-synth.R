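test_that("location generation honours counts, totals, flags and determinism", {
  loc <- generate_locations(synth_config(), seed = 1)
  expect_equal(nrow(loc), 47)
  expect_equal(sum(loc$role == "center"), 46)
  expect_equal(sum(loc$population_18plus), 301975)
  expect_equal(sum(loc$high_infection), 5)
  # flagged are the most populous
  cen <- loc[loc$role == "center", ]
  expect_true(min(cen$population_18plus[cen$high_infection]) >=
                max(cen$population_18plus[!cen$high_infection]))
  bb <- synth_config()$bbox
  expect_true(all(cen$lat >= bb[1] & cen$lat <= bb[2]))
  expect_true(all(cen$lon >= bb[3] & cen$lon <= bb[4]))
  expect_identical(loc, generate_locations(synth_config(), seed = 1))
  expect_false(identical(loc, generate_locations(synth_config(), seed = 2)))

  solo <- generate_locations(synth_config(n_centers = 1, n_high_infection = 1),
                             seed = 4)
  expect_equal(solo$population_18plus[solo$role == "center"], 301975)
})

test_that("demand allocation follows the uplift rule and conserves weekly totals", {
  # two equal-population centers, one flagged, uplift 20%, no noise
  loc <- make_locations(0:2, c("dc", "a", "b"), c(60, 60.5, 61), rep(10, 3),
                        c("depot", "center", "center"), c(0, 1000, 1000),
                        c(FALSE, TRUE, FALSE), c(NA, 1L, 2L))
  cfg <- synth_config(n_centers = 2, n_high_infection = 1, sigma = 0,
                      n_weeks = 1, weekly_base = 220, uplift_fraction = 0.2)
  dem <- generate_demand(cfg, loc, seed = 1)
  expect_equal(dem$doses, c(120L, 100L))

  # uplift 0, sigma 0: exactly proportional to population
  loc$high_infection <- FALSE
  loc$population_18plus <- c(0, 3000, 1000)
  cfg0 <- synth_config(n_centers = 2, n_high_infection = 0, sigma = 0,
                       n_weeks = 1, weekly_base = 400, uplift_fraction = 0)
  expect_equal(generate_demand(cfg0, loc, seed = 1)$doses, c(300L, 100L))

  # conservation + scale equivariance on the full generator
  cfg46 <- synth_config()
  loc46 <- generate_locations(cfg46, seed = 2)
  dem46 <- generate_demand(cfg46, loc46, seed = 9)
  wk <- tapply(dem46$doses, dem46$week, sum)
  expect_equal(as.integer(wk), as.integer(attr(dem46, "weekly_totals")))
  loc_scaled <- loc46
  loc_scaled$population_18plus <- loc_scaled$population_18plus * 2
  expect_equal(generate_demand(cfg46, loc_scaled, seed = 9)$doses,
               dem46$doses)
})

test_that("lognormal share noise has the closed-form mean", {
  cfg <- synth_config(n_centers = 1, n_weeks = 10000, sigma = 0.3,
                      weekly_growth = 0, n_high_infection = 0)
  loc <- generate_locations(cfg, seed = 5)
  dem <- generate_demand(cfg, loc, seed = 6)
  m <- mean(attr(dem, "noise"))
  expect_lt(abs(m - exp(0.3^2 / 2)) / exp(0.3^2 / 2), 0.02)
})

test_that("customer grouping splits by distance to the DC", {
  # all centers coincident with the DC -> all group 1
  loc <- make_locations(0:3, letters[1:4], rep(60, 4), rep(10, 4),
                        c("depot", rep("center", 3)), c(0, 1, 1, 1),
                        rep(FALSE, 4), rep(NA_integer_, 4))
  expect_equal(assign_customer_groups(loc), c(NA, 1L, 1L, 1L))

  # two centers at ~10 and ~500 km -> one per group
  deg <- 1 / (6371 * pi / 180)
  loc2 <- make_locations(0:2, c("dc", "near", "far"),
                         c(60, 60 + 10 * deg, 60 + 500 * deg), rep(10, 3),
                         c("depot", "center", "center"), c(0, 1, 1),
                         rep(FALSE, 3), rep(NA_integer_, 3))
  expect_equal(assign_customer_groups(loc2), c(NA, 1L, 2L))

  # 46 random centers: full cover and distance consistency
  loc46 <- generate_locations(synth_config(), seed = 3)
  g <- assign_customer_groups(loc46)
  expect_equal(sum(g == 1, na.rm = TRUE) + sum(g == 2, na.rm = TRUE), 46)
  d <- haversine_km(loc46$lat[1], loc46$lon[1], loc46$lat[-1], loc46$lon[-1])
  expect_lt(max(d[g[-1] == 1]), min(d[g[-1] == 2]))
})

test_that("packaged catalogue and scenario fixtures carry the case-study values", {
  veh <- default_vehicles()
  expect_equal(veh$name, c("e-NV200", "NV200", "VW Transporter"))
  expect_equal(veh$capacity_m3, c(2.1, 2.1, 6.7))
  expect_equal(veh$range_km, c(300, 1000, 1000))
  expect_equal(veh$var_cost_per_km, c(6, 8, 10))
  expect_equal(veh$emission_g_per_km, c(0, 131, 159))
  expect_true(all(veh$fixed_cost == 1500))
  expect_true(all(veh$speed_min == 40 & veh$speed_mode == 50 &
                    veh$speed_max == 70))

  sc <- default_scenarios()
  expect_length(sc, 10)
  expect_equal(sc[[1]]$model_id, 1)
  expect_equal(sc[[1]]$fleet, c("e-NV200" = 1, "NV200" = 2))
  expect_equal(sc[[7]]$model_id, 2)
  expect_equal(sc[[7]]$fleet, c("e-NV200" = 4, "NV200" = 3))
  expect_equal(sc[[10]]$model_id, 3)
  expect_equal(sc[[10]]$fleet, c("NV200" = 3, "VW Transporter" = 3))
})

test_that("largest-remainder rounding conserves totals and respects shares", {
  set.seed(21)
  for (i in 1:20) {
    x <- runif(sample(2:40, 1))
    tot <- sample(0:5000, 1)
    y <- largest_remainder(x, tot)
    expect_equal(sum(y), tot)
    expect_true(all(abs(y - x / sum(x) * tot) < 1))
  }
})
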