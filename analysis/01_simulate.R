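# Stage 1: generate the synthetic study system — a winter upwelling
# domain with an offshore island rookery, and ten individuals whose trips
# prefer cool, shallow water — and write both to disk for the later
# stages.

source("analysis/00_config.R")

env <- generate_env_fields(COND$scenario)
print(env)

tracks <- generate_tracks(env, COLONY, COND$truth,
                          n_individuals = COND$n_individuals,
                          trips_per_individual = COND$trips_per_individual,
                          seed = COND$track_seed,
                          step_km_mean = COND$step_km_mean,
                          step_km_sd = COND$step_km_sd)

write_fields_csv(env, file.path(OUT, "fields.csv"))
write_tracks_csv(tracks, file.path(OUT, "tracks.csv"))

n_pos <- sum(vapply(tracks, nrow, 0L))
cat(sprintf("wrote %d individuals, %d positions, %d daily fields\n",
            length(tracks), n_pos, length(env$time)))
cat(sprintf("domain SST %.1f-%.1f C, depth to %.0f m\n",
            min(env$vars$sst), max(env$vars$sst),
            min(env$static$bathymetry)))
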