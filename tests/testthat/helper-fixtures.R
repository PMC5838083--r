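# Shared fixtures, built in code: a small environmental world, simple
# geometric trips, and hand-rolled matchup tables.

small_env <- function(seed = 7, noise = TRUE, n_eddies = 4,
                      date_range = as.Date(c("2006-11-01", "2006-11-20"))) {
  noise_sd <- if (noise) list(sst = 0.3, chl_log10 = 0.1, sla = 0.5,
                              wind_v = 1)
  else list(sst = 0, chl_log10 = 0, sla = 0, wind_v = 0)
  generate_env_fields(env_scenario(
    lon_range = c(-124, -118.5), lat_range = c(32, 36), grid_step = 0.25,
    date_range = date_range, island = c(-120.25, 34),
    n_eddies = n_eddies, noise_sd = noise_sd, seed = seed))
}

# a trip object from bare positions (daily dates starting 2006-11-02)
make_trip <- function(lon, lat, colony, trip_id = "a1_t01",
                      animal_id = "a1") {
  pos <- data.frame(animal_id = animal_id,
                    date = as.Date("2006-11-02") + seq_along(lon) - 1,
                    lon = lon, lat = lat)
  structure(list(trip_id = trip_id, animal_id = animal_id, colony = colony,
                 positions = pos, start_date = min(pos$date),
                 end_date = max(pos$date)), class = "trip")
}

make_phase <- function(lon, lat, phase = "outgoing", trip_id = "a1_t01") {
  structure(list(trip_id = trip_id, animal_id = "a1", phase = phase,
                 colony = c(lon[1], lat[1]),
                 positions = data.frame(
                   date = as.Date("2006-11-02") + seq_along(lon) - 1,
                   lon = lon, lat = lat)), class = "trip_phase")
}

make_nd <- function(distance_km, bearing_deg) {
  structure(list(distance_km = distance_km, bearing_deg = bearing_deg),
            class = "net_displacement")
}

# a synthetic scored simulation with a given weight / land flag
make_sim <- function(weight, land = FALSE, sim_id = 1L) {
  structure(list(trip_id = "a1_t01", phase = "outgoing", sim_id = sim_id,
                 positions = data.frame(date = as.Date("2006-11-02"),
                                        lon = 0, lat = 0),
                 land_violation = land, weight = weight), class = "crw_sim")
}

# a minimal matchup table for assembly tests: each trip contributes
# n_days presence rows and the same count for each of n_sims nulls
make_matchup <- function(ids, trips_per_id = 2, n_days = 5, n_sims = 3) {
  rows <- list()
  for (a in ids) for (tr in seq_len(trips_per_id)) {
    days <- as.Date("2006-11-01") + seq_len(n_days + tr) - 1
    base <- data.frame(animal_id = a,
                       trip_id = sprintf("%s_t%02d", a, tr),
                       date = days, lon = -121 + stats::runif(length(days)),
                       lat = 33.5 + stats::runif(length(days)),
                       sst = stats::rnorm(length(days), 15),
                       bathymetry = stats::rnorm(length(days), -2000, 300),
                       dist_colony_km = stats::runif(length(days), 5, 100))
    rows[[length(rows) + 1]] <- cbind(source = "presence",
                                      sim_id = NA_integer_, base)
    for (s in seq_len(n_sims))
      rows[[length(rows) + 1]] <- cbind(source = "pseudoabsence",
                                        sim_id = s, base)
  }
  do.call(rbind, rows)
}
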