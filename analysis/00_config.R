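# Shared settings for the analysis scripts. Everything flows from one
# master seed; stage outputs accumulate under results/analysis/.

library(crwhabitat)

MASTER_SEED <- 1L
OUT <- file.path("results", "analysis")
dir.create(OUT, recursive = TRUE, showWarnings = FALSE)

COND <- study_conditions("strong")
COLONY <- COND$colony
COVARIATES <- COND$covariates
CANDIDATES <- list(
  environmental = c("sst", "chl", "eke", "sla", "sla_sd", "bathymetry"),
  distance = c("sst", "chl", "eke", "sla", "sla_sd", "dist_colony_km"))
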