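# End-to-end orchestration: simulate/load -> preprocess -> CRW null ->
# matchup -> fit/ensemble -> predict, with one master seed, per-stage
# logging and a run manifest.

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Default pipeline configuration
#'
#' Returns the full parameter list for [run_pipeline()], documenting every
#' tunable: speed-filter `vmax` (m/s), haul-out radius (km), interpolation
#' gap tolerance (days), CRW simulations per phase, matchup box edge
#' (deg), smooth basis dimension, ensemble size and alpha, prediction
#' grid step (deg) and number of predicted days, and the candidate
#' covariate sets (the 6-covariate environmental model and the
#' distance-from-colony competitor).
#'
#' @return Named list of defaults; override entries via the `config`
#'   argument of [run_pipeline()].
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    scenario = list(),          # env_scenario() overrides
    colony = NULL,              # c(lon, lat); required
    truth = list(intercept = 0, terms = list()),
    n_individuals = 10, trips_per_individual = 2,
    vmax = 3, haulout_radius_km = 5, gap_max_days = 3,
    n_sims = 10,
    box_deg = 1.0,
    k = 4, n_runs = 40, alpha = 0.001,
    covariates = c("sst", "chl", "eke", "sla", "sla_sd", "bathymetry"),
    candidates = list(
      environmental = c("sst", "chl", "eke", "sla", "sla_sd", "bathymetry"),
      distance = c("sst", "chl", "eke", "sla", "sla_sd", "dist_colony_km")),
    predict_grid_step = 0.25, n_predict_days = 6,
    select_candidates = FALSE)
}

load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$colony) || length(cfg$colony) != 2)
    stop("config must provide colony = c(lon, lat)")
  if (is.null(cfg$out_dir)) stop("config must provide out_dir")
  cfg$colony <- as.numeric(cfg$colony)
  cfg
}

#' Preprocess raw tracks into daily trips
#'
#' Speed filter, daily regularization against the land mask, and trip
#' segmentation for every individual.
#'
#' @param tracks A `raw_tracks` list.
#' @param env `env_fields` land mask.
#' @param colony `c(lon, lat)`.
#' @param vmax,haulout_radius_km,gap_max_days Stage parameters.
#' @return List of `trip` objects across all individuals.
#' @export
preprocess_tracks <- function(tracks, env, colony, vmax = 3,
                              haulout_radius_km = 5, gap_max_days = 3) {
  trips <- list()
  for (tr in tracks) {
    filt <- speed_filter(tr, vmax)
    daily <- regularize_daily(filt, env, gap_max_days)
    trips <- c(trips, segment_trips(daily, colony, haulout_radius_km, env))
  }
  trips
}

# daily presence positions of a trip list as one data.frame
trips_to_presences <- function(trips) {
  do.call(rbind, lapply(trips, function(tr)
    data.frame(animal_id = tr$animal_id, trip_id = tr$trip_id,
               sim_id = NA_integer_, date = tr$positions$date,
               lon = tr$positions$lon, lat = tr$positions$lat)))
}

# run the CRW stage for every trip; returns pseudoabsence positions for
# every retained paired null (sim_id indexes the pair) plus the weights
crw_stage <- function(trips, env, n_sims, seed) {
  seeds <- split_seed(seed, length(trips))
  abs_rows <- list(); weights <- list()
  for (i in seq_along(trips)) {
    res <- crw_null_for_trip(trips[[i]], env, n_sims, seeds[i])
    weights[[i]] <- res$weights
    for (j in seq_along(res$paired))
      abs_rows[[length(abs_rows) + 1]] <- data.frame(
        animal_id = trips[[i]]$animal_id, trip_id = trips[[i]]$trip_id,
        sim_id = j, date = res$paired[[j]]$date,
        lon = res$paired[[j]]$lon, lat = res$paired[[j]]$lat)
  }
  list(pseudoabsences = do.call(rbind, abs_rows),
       weights = do.call(rbind, weights))
}

#' Run the full pipeline
#'
#' Executes simulate -> preprocess -> CRW -> matchup -> fit/ensemble ->
#' predict under a single master seed, writes every stage output under
#' `out_dir` and returns (and writes) a manifest of parameters, seeds and
#' per-stage record counts. Re-running with the same config and seed
#' reproduces every output.
#'
#' @param config Named list (or YAML path) overriding [default_config()];
#'   `colony` and `out_dir` are required.
#' @return The manifest, invisibly; stage outputs live under `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- split_seed(cfg$seed, 6)
  manifest <- list(package_version = as.character(utils::packageVersion("crwhabitat")),
                   master_seed = cfg$seed, stage_seeds = seeds,
                   parameters = cfg[setdiff(names(cfg), "out_dir")],
                   counts = list())

  stage_log("simulate", "generating fields and tracks (seed %d)", cfg$seed)
  sc_args <- utils::modifyList(list(seed = seeds[1]), cfg$scenario)
  scenario <- do.call(env_scenario, sc_args)
  env <- generate_env_fields(scenario)
  truth <- truth_preference(cfg$truth$intercept, cfg$truth$terms)
  tracks <- generate_tracks(env, cfg$colony, truth,
                            n_individuals = cfg$n_individuals,
                            trips_per_individual = cfg$trips_per_individual,
                            seed = seeds[2])
  write_tracks_csv(tracks, file.path(cfg$out_dir, "tracks.csv"))
  manifest$counts$raw_positions <- sum(vapply(tracks, nrow, 0L))

  stage_log("preprocess", "filtering, regularizing, segmenting %d tracks",
            length(tracks))
  trips <- preprocess_tracks(tracks, env, cfg$colony, cfg$vmax,
                             cfg$haulout_radius_km, cfg$gap_max_days)
  # single-position trips carry no step structure for the null model
  trips <- Filter(function(tr) nrow(tr$positions) >= 2, trips)
  if (length(trips) == 0) stop("preprocess: no trips recovered")
  metrics <- do.call(rbind, lapply(trips, function(tr) {
    m <- trip_metrics(tr)
    data.frame(trip_id = tr$trip_id, animal_id = tr$animal_id,
               start_date = tr$start_date, end_date = tr$end_date,
               duration_days = m$duration_days,
               max_distance_km = m$max_distance_km,
               total_distance_km = m$total_distance_km)
  }))
  utils::write.csv(metrics, file.path(cfg$out_dir, "trips.csv"),
                   row.names = FALSE)
  manifest$counts$trips <- length(trips)

  stage_log("crw", "simulating %d nulls per phase for %d trips",
            cfg$n_sims, length(trips))
  crw <- crw_stage(trips, env, cfg$n_sims, seeds[3])
  utils::write.csv(crw$weights, file.path(cfg$out_dir, "crw_weights.csv"),
                   row.names = FALSE)
  manifest$counts$crw_sims <- nrow(crw$weights)
  manifest$counts$crw_retained <- sum(crw$weights$retained)

  stage_log("matchup", "extracting covariates")
  presences <- trips_to_presences(trips)
  matchup <- build_matchup_table(presences, crw$pseudoabsences, env,
                                 cfg$colony, cfg$box_deg)
  utils::write.csv(matchup, file.path(cfg$out_dir, "matchup.csv"),
                   row.names = FALSE)
  manifest$counts$matchup_records <- nrow(matchup)
  manifest$counts$matchup_excluded <- attr(matchup, "n_excluded")

  stage_log("fit", "assembling 1:1 dataset and fitting")
  tab <- assemble_dataset(matchup, seed = seeds[4])
  manifest$counts$model_presences <- sum(tab$presence == 1)
  manifest$counts$model_pseudoabsences <- sum(tab$presence == 0)
  gvif <- tryCatch(gvif_check(tab, cfg$covariates), error = function(e) NULL)
  if (!is.null(gvif))
    utils::write.csv(gvif, file.path(cfg$out_dir, "gvif.csv"),
                     row.names = FALSE)
  if (isTRUE(cfg$select_candidates)) {
    sel <- select_model(cfg$candidates, tab, cfg$k)
    covs <- cfg$candidates[[sel$best]]
    utils::write.csv(sel$ranking, file.path(cfg$out_dir, "selection.csv"),
                     row.names = FALSE)
  } else covs <- cfg$covariates
  fit <- fit_binomial_gamm(tab, covs, cfg$k)
  jsonlite::write_json(
    list(covariates = covs, aic = fit$aic, auc = fit$auc,
         deviance_explained = fit$deviance_explained,
         re_variance = fit$re_variance, smooth_table = fit$smooth_table),
    file.path(cfg$out_dir, "fit.json"), auto_unbox = TRUE, digits = 10)
  pr <- do.call(rbind, lapply(names(fit$partial), function(v)
    cbind(covariate = v, fit$partial[[v]])))
  utils::write.csv(pr, file.path(cfg$out_dir, "partial_response.csv"),
                   row.names = FALSE)

  stage_log("ensemble", "running %d resampled fits", cfg$n_runs)
  ens <- run_ensemble(matchup, covs, cfg$n_runs, cfg$alpha, seeds[5], cfg$k)
  jsonlite::write_json(
    list(n_runs = ens$n_runs, alpha = ens$alpha,
         smooth_summary = ens$smooth_summary, metrics = ens$metrics),
    file.path(cfg$out_dir, "ensemble.json"), auto_unbox = TRUE, digits = 10)

  stage_log("predict", "gridding %d daily surfaces at %.2f deg",
            cfg$n_predict_days, cfg$predict_grid_step)
  dates <- env$time[unique(round(seq(1, length(env$time),
                                     length.out = cfg$n_predict_days)))]
  surfaces <- lapply(dates, function(d)
    predict_daily(fit, env, d, cfg$predict_grid_step, cfg$colony,
                  cfg$box_deg))
  comp <- seasonal_composite(surfaces)
  write_surface_csv(comp, file.path(cfg$out_dir, "suitability_mean.csv"),
                    "mean")
  write_surface_csv(comp, file.path(cfg$out_dir, "suitability_se.csv"), "se")
  manifest$counts$predicted_days <- length(surfaces)

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, null = "null")
  stage_log("done", "outputs in %s", cfg$out_dir)
  invisible(manifest)
}
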