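# Stage 2: speed-filter and regularize the raw tracks to one position
# per day, segment foraging trips between haul-outs, summarize trip
# metrics, and map the population's core (50%) and home-range (95%)
# utilization areas.

source("analysis/00_config.R")

env <- read_fields_csv(file.path(OUT, "fields.csv"))
tracks <- read_tracks_csv(file.path(OUT, "tracks.csv"))

trips <- preprocess_tracks(tracks, env, COLONY)
trips <- Filter(function(tr) nrow(tr$positions) >= 2, trips)

metrics <- do.call(rbind, lapply(trips, function(tr) {
  m <- trip_metrics(tr)
  data.frame(trip_id = tr$trip_id, animal_id = tr$animal_id,
             start_date = tr$start_date, end_date = tr$end_date,
             duration_days = m$duration_days,
             max_distance_km = m$max_distance_km,
             total_distance_km = m$total_distance_km)
}))
write.csv(metrics, file.path(OUT, "trips.csv"), row.names = FALSE)

at_sea <- do.call(rbind, lapply(trips, `[[`, "positions"))
ud <- kernel_ud(at_sea$lon, at_sea$lat)
write_ud_geojson(ud, file.path(OUT, "ud_contours.geojson"))

cat(sprintf("%d trips from %d individuals\n", nrow(metrics),
            length(unique(metrics$animal_id))))
cat(sprintf("trip duration %.1f +/- %.1f d; max distance %.0f km (range %.0f-%.0f)\n",
            mean(metrics$duration_days), sd(metrics$duration_days),
            mean(metrics$max_distance_km), min(metrics$max_distance_km),
            max(metrics$max_distance_km)))
cat(sprintf("UD areas: 50%% %.0f km2, 95%% %.0f km2\n",
            ud$areas_km2[["50%"]], ud$areas_km2[["95%"]]))
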