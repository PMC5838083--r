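test_that("observed step series follow the stated sign conventions", {
  # three collinear eastward positions: zero turning angle
  ph <- make_phase(c(0, 0.5, 1), c(0, 0, 0))
  ss <- observed_steps(ph)
  expect_equal(length(ss$step_km), 2)
  expect_equal(ss$turn_deg, 0, tolerance = 1e-6)

  # east then due north: a left turn of 90 degrees
  ph2 <- make_phase(c(0, 0.5, 0.5), c(0, 0, 0.5))
  expect_equal(observed_steps(ph2)$turn_deg, -90, tolerance = 1e-3)

  # closed equilateral triangle at small scale: equal sides, |turn| = 120
  h <- 0.1
  tri <- make_phase(c(0, h, h / 2, 0),
                    c(0, 0, h * sqrt(3) / 2, 0))
  st <- observed_steps(tri)
  expect_equal(max(st$step_km) / min(st$step_km), 1, tolerance = 1e-3)
  expect_equal(abs(st$turn_deg), c(120, 120), tolerance = 0.5)

  expect_error(observed_steps(make_phase(0, 0)), ">= 2")
})

test_that("open-ocean simulations preserve the step-length multiset", {
  ph <- make_phase(c(-123, -122.8, -122.5, -122.45, -122.6),
                   c(34, 34.2, 34.1, 33.9, 33.7))
  obs <- sort(observed_steps(ph)$step_km)
  sims <- simulate_crw(ph, env = NULL, n_sims = 20, seed = 5)
  for (s in sims) {
    expect_false(s$land_violation)
    got <- sort(observed_steps(list(positions = s$positions))$step_km)
    expect_equal(got, obs, tolerance = 1e-9)
    expect_equal(nrow(s$positions), nrow(ph$positions))
    expect_equal(as.numeric(s$positions[1, c("lon", "lat")]),
                 c(ph$positions$lon[1], ph$positions$lat[1]))
  }
})

test_that("zero angular spread produces straight-line simulations", {
  ph <- make_phase(seq(-123, -122, length.out = 6), rep(0, 6))
  expect_equal(crwhabitat:::circular_stats(observed_steps(ph)$turn_deg)$sd, 0)
  sims <- simulate_crw(ph, env = NULL, n_sims = 5, seed = 9)
  len_obs <- sum(observed_steps(ph)$step_km)
  for (s in sims) {
    nd <- net_displacement(s$positions)
    expect_equal(nd$distance_km, len_obs, tolerance = len_obs * 1e-4)
  }
})

test_that("simulation sets are reproducible and respect the land mask", {
  env <- small_env()
  ph <- make_phase(c(-120.7, -120.9, -121.2, -121.0, -120.8),
                   c(34, 34.15, 34.2, 33.95, 33.8))
  s1 <- simulate_crw(ph, env, n_sims = 12, seed = 33)
  s2 <- simulate_crw(ph, env, n_sims = 12, seed = 33)
  expect_identical(lapply(s1, `[[`, "positions"),
                   lapply(s2, `[[`, "positions"))
  for (s in s1)
    if (!s$land_violation)
      expect_false(any(is_land(env, s$positions$lon, s$positions$lat)))
  on_land <- make_phase(c(-118.6, -118.7), c(33, 33.1))
  expect_error(simulate_crw(on_land, env, n_sims = 2), "on land")
})

test_that("net displacement reports haversine distance and bearing", {
  same <- data.frame(lon = c(3, 3), lat = c(7, 7))
  nd0 <- net_displacement(same)
  expect_equal(nd0$distance_km, 0)
  expect_equal(nd0$bearing_deg, 0)
  north <- net_displacement(data.frame(lon = c(0, 0), lat = c(0, 2)))
  expect_equal(north$bearing_deg, 0)
  east <- net_displacement(data.frame(lon = c(0, 1), lat = c(0, 0)))
  expect_equal(east$distance_km, 111.19, tolerance = 1e-4)
  expect_equal(east$bearing_deg, 90, tolerance = 1e-6)
})

test_that("the similarity weight evaluates its formula literally", {
  expect_equal(crw_weight(make_nd(123, 77), make_nd(123, 77)), 0)
  expect_equal(crw_weight(make_nd(100, 0), make_nd(80, 45)), 0.9)
  # bearings 10 vs 190: difference wraps to 180
  expect_equal(crw_weight(make_nd(100, 10), make_nd(100, 190)), 2)
  expect_error(crw_weight(make_nd(0, 0), make_nd(10, 0)), "degenerate")
  # documented alternative readings
  expect_equal(crw_weight(make_nd(100, 0), make_nd(80, 45),
                          scale_whole_sum = TRUE), 2 * (0.2 + 0.5))
  expect_equal(crw_weight(make_nd(100, 0), make_nd(120, 0),
                          absolute_distance = TRUE), 0.4)
  # longer-than-track simulations lower the signed weight monotonically
  w <- vapply(seq(20, 180, by = 20), function(ds)
    crw_weight(make_nd(100, 0), make_nd(ds, 30)), 0)
  expect_true(all(diff(w) < 0))
  # the bearing term alone stays within [0, 2]
  bw <- vapply(0:359, function(b)
    crw_weight(make_nd(100, 0), make_nd(100, b)), 0)
  expect_true(all(bw >= 0 & bw <= 2))
})

test_that("the quartile filter drops land crossers then the worst quartile", {
  sims <- lapply(1:8, function(i) make_sim(i, sim_id = i))
  kept <- filter_sims(sims)
  expect_equal(vapply(kept, `[[`, 0, "weight"), 1:6)  # 75th pct = 6.25

  equal <- lapply(1:5, function(i) make_sim(2.5, sim_id = i))
  expect_length(filter_sims(equal), 5)

  with_land <- c(lapply(1:4, function(i) make_sim(i, sim_id = i)),
                 list(make_sim(0.1, land = TRUE, sim_id = 5L)))
  kept2 <- filter_sims(with_land)
  expect_false(any(vapply(kept2, `[[`, TRUE, "land_violation")))
  expect_length(kept2, 3)

  only_land <- list(make_sim(1, land = TRUE))
  expect_error(filter_sims(only_land), "land")
  unscored <- list(make_sim(NA_real_))
  expect_error(filter_sims(unscored), "scored")
})

test_that("pseudoabsence selection is uniform and seeded", {
  one <- list(make_sim(1))
  expect_identical(select_pseudoabsence(one, 3), one[[1]])
  four <- lapply(1:4, function(i) make_sim(i, sim_id = i))
  expect_identical(select_pseudoabsence(four, 7),
                   select_pseudoabsence(four, 7))
  picks <- vapply(1:10000, function(s)
    select_pseudoabsence(four, s)$sim_id, 0L)
  freq <- tabulate(picks, 4) / 10000
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(freq - 0.25) < 3 * se + 1e-9))
  expect_error(select_pseudoabsence(list(), 1), "no retained")
})

test_that("paired null trips match the source trip's position count", {
  env <- small_env()
  colony <- c(-120.5, 34)
  tr <- make_trip(c(-120.6, -121.0, -121.4, -121.1, -120.7),
                  c(34, 34.2, 34.3, 34.1, 33.95), colony)
  res <- crw_null_for_trip(tr, env, n_sims = 10, seed = 3)
  expect_gt(length(res$paired), 0)
  for (p in res$paired) {
    expect_equal(nrow(p), nrow(tr$positions))
    expect_false(any(is_land(env, p$lon, p$lat)))
  }
  expect_true(all(c("trip_id", "phase", "sim_id", "weight", "retained")
                  %in% names(res$weights)))
})
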