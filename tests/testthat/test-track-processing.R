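ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

test_that("speed filter removes only positions that are too fast", {
  slow <- data.frame(timestamp = ts_utc("2006-11-01") + (0:5) * 21600,
                     lon = -121 + (0:5) * 0.1, lat = 34)
  expect_identical(speed_filter(slow, vmax = 3), slow)

  # middle position implies ~50 m/s against both neighbours
  spike <- data.frame(timestamp = ts_utc("2006-11-01") + (0:2) * 3600,
                      lon = c(-121, -119.2, -121.02), lat = 34)
  out <- speed_filter(spike, vmax = 3)
  expect_equal(nrow(out), 2)
  expect_equal(out$lon, c(-121, -121.02))

  moving <- data.frame(timestamp = ts_utc("2006-11-01") + (0:4) * 21600,
                       lon = -121 + (0:4) * 0.2, lat = 34)
  expect_equal(nrow(speed_filter(moving, vmax = 0)), 1)
})

test_that("daily regularization interpolates linearly and is idempotent", {
  daily_in <- data.frame(
    animal_id = "a1",
    timestamp = ts_utc("2006-11-01") + (0:4) * 86400,
    lon = c(-121, -121.2, -121.4, -121.1, -120.9), lat = 34 + (0:4) * 0.1)
  out <- regularize_daily(daily_in)
  expect_equal(out$lon, daily_in$lon)
  expect_equal(out$lat, daily_in$lat)

  # two fixes two days apart: the intermediate day is the linear midpoint
  two <- data.frame(animal_id = "a1",
                    timestamp = ts_utc("2006-11-01") + c(0, 2) * 86400,
                    lon = c(-122, -121), lat = c(33, 34))
  mid <- regularize_daily(two)
  expect_equal(nrow(mid), 3)
  expect_equal(mid$lon[2], -121.5)
  expect_equal(mid$lat[2], 33.5)

  # re-running on its own output is the identity
  again <- regularize_daily(mid)
  expect_equal(again$lon, mid$lon)
  expect_equal(again$date, mid$date)

  # gaps wider than the tolerance are not bridged
  gap <- data.frame(animal_id = "a1",
                    timestamp = ts_utc("2006-11-01") + c(0, 5) * 86400,
                    lon = c(-122, -121), lat = c(33, 34))
  expect_equal(nrow(regularize_daily(gap, gap_max_days = 3)), 2)
})

test_that("interpolated positions over land are dropped", {
  env <- small_env()
  crossing <- data.frame(animal_id = "a1",
                         timestamp = ts_utc("2006-11-05") + c(0, 4) * 86400,
                         lon = c(-120.5, -118.6), lat = 33)
  out <- regularize_daily(crossing, env, gap_max_days = 5)
  expect_false(any(is_land(env, out$lon, out$lat)))
  expect_lt(nrow(out), 5)
})

test_that("trip segmentation keeps interior at-sea runs only", {
  colony <- c(-120.5, 34)
  # state sequence H H S S S H S S H
  off <- c(0, 0, 0.5, 0.6, 0.7, 0.02, 0.5, 0.6, 0)
  daily <- data.frame(animal_id = "a1",
                      date = as.Date("2006-11-01") + seq_along(off) - 1,
                      lon = colony[1] - off, lat = colony[2])
  trips <- segment_trips(daily, colony, haulout_radius_km = 5)
  expect_length(trips, 2)
  expect_equal(nrow(trips[[1]]$positions), 3)
  expect_equal(nrow(trips[[2]]$positions), 2)
  expect_false(any(duplicated(c(trips[[1]]$positions$date,
                                trips[[2]]$positions$date))))

  all_home <- data.frame(animal_id = "a1",
                         date = as.Date("2006-11-01") + 0:4,
                         lon = colony[1], lat = colony[2])
  expect_length(segment_trips(all_home, colony), 0)
})

test_that("phase splitting puts the apex at the earliest maximum", {
  colony <- c(-120.5, 34)
  # out-and-back with distances roughly 10, 50, 90, 60, 20 km west
  km2deg <- 1 / (111.19 * cos(34 * pi / 180))
  tr <- make_trip(colony[1] - c(10, 50, 90, 60, 20) * km2deg,
                  rep(34, 5), colony)
  ph <- split_phases(tr)
  expect_equal(nrow(ph[[1]]$positions), 3)   # start..apex
  expect_equal(nrow(ph[[2]]$positions), 3)   # apex..end
  expect_equal(ph[[1]]$positions$lon[3], ph[[2]]$positions$lon[1])

  # tie: earliest index wins
  tie <- make_trip(colony[1] - c(10, 90, 90, 20) * km2deg, rep(34, 4), colony)
  ph2 <- split_phases(tie)
  expect_equal(nrow(ph2[[1]]$positions), 2)

  two <- make_trip(colony[1] - c(10, 50) * km2deg, rep(34, 2), colony)
  ph3 <- split_phases(two)
  expect_equal(nrow(ph3[[1]]$positions), 2)
  expect_equal(nrow(ph3[[2]]$positions), 1)
})

test_that("trip metrics agree with hand-computed haversine values", {
  colony <- c(-120.5, 34)
  p50 <- as.numeric(destination_point(colony, 270, 50))
  tr <- make_trip(c(colony[1], p50[1], colony[1]),
                  c(colony[2], p50[2], colony[2]), colony)
  m <- trip_metrics(tr)
  expect_equal(m$max_distance_km, 50, tolerance = 1e-6)
  expect_equal(m$total_distance_km, 100, tolerance = 1e-6)

  still <- make_trip(rep(-121, 4), rep(34, 4), colony)
  expect_equal(trip_metrics(still)$total_distance_km, 0)
  expect_equal(trip_metrics(make_trip(-121 - (1:8) * 0.05, rep(34, 8),
                                      colony))$duration_days, 8)
})

test_that("path length dominates displacement for random trips", {
  set.seed(23)
  colony <- c(-120.5, 34)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    tr <- make_trip(colony[1] + cumsum(stats::rnorm(n, 0, 0.1)),
                    colony[2] + cumsum(stats::rnorm(n, 0, 0.1)), colony)
    m <- trip_metrics(tr)
    d0 <- great_circle_km(colony, c(tr$positions$lon[1], tr$positions$lat[1]))
    expect_lte(m$max_distance_km, m$total_distance_km + d0 + 1e-9)
    expect_equal(m$duration_days, n)
  }
})

test_that("kernel UD contours have normal-theory areas and nest", {
  set.seed(17)
  n <- 1000
  lon <- -121 + stats::rnorm(n, 0, 0.3)
  lat <- 34 + stats::rnorm(n, 0, 0.3 / cos(34 * pi / 180))
  ud <- kernel_ud(lon, lat)
  expect_equal(sum(ud$mass), 1, tolerance = 1e-9)
  a50 <- ud$areas_km2[["50%"]]; a95 <- ud$areas_km2[["95%"]]
  expect_lt(a50, a95)
  # isotropic normal: area ratio equals the chi-square quantile ratio,
  # inflated identically by the kernel bandwidth
  expect_lt(abs(a95 / a50 - stats::qchisq(.95, 2) / stats::qchisq(.50, 2)),
            0.2 * stats::qchisq(.95, 2) / stats::qchisq(.50, 2))
  expect_error(kernel_ud(lon[1:4], lat[1:4]), "at least 5")
})

test_that("well-separated clusters split the home-range contour", {
  set.seed(19)
  lon <- c(stats::rnorm(300, -122, 0.1), stats::rnorm(300, -119.5, 0.1))
  lat <- c(stats::rnorm(300, 33, 0.1), stats::rnorm(300, 35, 0.1))
  ud <- kernel_ud(lon, lat)
  expect_gte(length(ud$contours[["95%"]]), 2)
})

test_that("the packaged trip table summarizes as published", {
  fx <- table1_fixture()
  expect_equal(nrow(fx), 72)
  s <- table1_summary(fx)
  expect_equal(s$stats$n, rep(72L, 3))
  expect_equal(unname(s$location_counts["San Nicolas"]), 55L)
  bad <- fx[, -3]
  expect_error(table1_summary(bad), "malformed")
})
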