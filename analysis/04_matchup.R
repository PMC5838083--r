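# Stage 4: join every presence and pseudoabsence daily position to the
# environmental fields by 1-degree box means, derive EKE from the
# box-averaged currents, apply the log/sqrt transforms, and write the
# modeling table.

source("analysis/00_config.R")

env <- read_fields_csv(file.path(OUT, "fields.csv"))
tracks <- read_tracks_csv(file.path(OUT, "tracks.csv"))
trips <- Filter(function(tr) nrow(tr$positions) >= 2,
                preprocess_tracks(tracks, env, COLONY))
pseudo <- read.csv(file.path(OUT, "pseudoabsences.csv"))
pseudo$date <- as.Date(pseudo$date)

presences <- do.call(rbind, lapply(trips, function(tr)
  data.frame(animal_id = tr$animal_id, trip_id = tr$trip_id,
             sim_id = NA_integer_, tr$positions[c("date", "lon", "lat")])))

matchup <- build_matchup_table(presences, pseudo, env, COLONY)
write.csv(matchup, file.path(OUT, "matchup.csv"), row.names = FALSE)

cat(sprintf("%d matchup records (%d presence, %d pseudoabsence), %d excluded\n",
            nrow(matchup), sum(matchup$source == "presence"),
            sum(matchup$source == "pseudoabsence"),
            attr(matchup, "n_excluded")))
for (v in c("sst", "chl", "eke", "bathymetry"))
  cat(sprintf("  %-11s %8.2f to %8.2f\n", v, min(matchup[[v]]),
              max(matchup[[v]])))
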