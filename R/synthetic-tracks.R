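# Preference-biased central-place forager tracks. Each individual
# alternates haul-out intervals at the rookery with at-sea trips; at-sea
# movement is a biased random walk whose step headings are chosen with
# probability proportional to exp(truth linear predictor) over candidate
# destinations, with a deterministic homeward drift over the second half
# of the trip so every trip closes at the rookery.

# candidate destinations: n_headings even headings at one drawn step length
step_candidates <- function(pos, step_km, n_headings = 16) {
  h <- seq(0, 360, length.out = n_headings + 1)[-(n_headings + 1)]
  dest <- destination_point(matrix(pos, nrow = n_headings, ncol = 2,
                                   byrow = TRUE), h, step_km)
  list(heading = h, lon = dest[, 1], lat = dest[, 2])
}

# one biased step; homeward is the rookery c(lon, lat) and drift_strength
# scales a cos(heading - bearing-home) pull added to the log-probability;
# candidates inside exclude_km of homeward are treated like land so the
# walk cannot graze the haul-out zone mid-trip
choose_next <- function(env, truth, pos, date, step_km,
                        homeward = NULL, drift_strength = 0,
                        exclude_km = 0) {
  cand <- step_candidates(pos, step_km)
  sea <- !is_land(env, cand$lon, cand$lat)
  if (exclude_km > 0 && !is.null(homeward)) {
    d_home <- great_circle_km(cbind(cand$lon, cand$lat),
                              matrix(homeward, length(cand$lon), 2,
                                     byrow = TRUE))
    sea <- sea & d_home > exclude_km
  }
  if (!any(sea)) return(NULL)
  eta <- truth_eta(env, truth, cand$lon[sea], cand$lat[sea], date)
  eta[!is.finite(eta)] <- min(eta[is.finite(eta)], 0)
  if (drift_strength > 0 && !is.null(homeward)) {
    b_home <- initial_bearing_deg(pos, homeward)
    eta <- eta + drift_strength *
      cos((cand$heading[sea] - b_home) * pi / 180)
  }
  p <- exp(eta - max(eta))
  k <- sample.int(sum(sea), 1, prob = p)
  idx <- which(sea)[k]
  c(lon = cand$lon[idx], lat = cand$lat[idx])
}

# preference-weighted foraging destination: a sea cell in the annulus
# [0.3 R, R] km around the colony, drawn with probability proportional to
# exp(truth eta); with a null truth this is uniform over the annulus
sample_destination <- function(env, truth, colony, reach_km, date) {
  g <- expand.grid(lon = env$lon, lat = env$lat)
  d <- great_circle_km(cbind(g$lon, g$lat),
                       matrix(colony, nrow(g), 2, byrow = TRUE))
  ok <- !is_land(env, g$lon, g$lat) & d >= 0.3 * reach_km & d <= reach_km
  if (!any(ok)) return(NULL)
  eta <- truth_eta(env, truth, g$lon[ok], g$lat[ok], date)
  eta[!is.finite(eta)] <- min(eta[is.finite(eta)], 0)
  p <- exp(eta - max(eta))
  k <- sample.int(sum(ok), 1, prob = p)
  c(g$lon[ok][k], g$lat[ok][k])
}

# trip durations on the observed scale: gamma with mean 8.4 d, SD 3.6 d,
# rounded and clipped to 2..23 days
draw_trip_duration <- function(n, mean_days = 8.4, sd_days = 3.6,
                               min_days = 2, max_days = 23) {
  shape <- (mean_days / sd_days)^2
  rate <- mean_days / sd_days^2
  pmin(max_days, pmax(min_days, round(stats::rgamma(n, shape, rate))))
}

#' Generate preference-biased central-place forager tracks
#'
#' Simulates `n_individuals` animals from a fixed rookery over the field
#' set's time span. Trips are biased random walks: at each sub-daily step
#' the heading is drawn over 16 candidate destinations with probability
#' proportional to `exp(eta)` where `eta` is the ground-truth linear
#' predictor at the candidate (plus, over the second half of the trip, a
#' homeward drift that closes the trip at the rookery). Candidates on land
#' are excluded. Trip durations are drawn from a gamma distribution with
#' mean 8.4 and SD 3.6 days, clipped to 2-23 days; trips are separated by
#' haul-out intervals at the rookery.
#'
#' @param env An `env_fields` object.
#' @param rookery `c(lon, lat)`; must lie inside the grid, on or adjacent
#'   to the coastline.
#' @param truth A [truth_preference()]; all-zero terms give unbiased walks.
#' @param n_individuals,trips_per_individual Counts.
#' @param seed Integer seed.
#' @param steps_per_day Sub-daily cadence (positions per day).
#' @param step_km_mean,step_km_sd Lognormal step-length scale (km per step).
#' @param haulout_days Days spent at the rookery between trips.
#' @return List of class `raw_tracks`: one data.frame per individual with
#'   columns `animal_id`, `timestamp` (POSIXct UTC), `lon`, `lat`, `lc`.
#' @export
generate_tracks <- function(env, rookery, truth,
                            n_individuals = 10, trips_per_individual = 2,
                            seed = 1L, steps_per_day = 4,
                            step_km_mean = 12, step_km_sd = 4,
                            haulout_days = 2) {
  ix <- grid_index(env, rookery[1], rookery[2])
  if (is.na(ix$i) || is.na(ix$j)) stop("rookery outside grid")
  near <- expand.grid(dlon = c(-1, 0, 1) * diff(env$lon[1:2]),
                      dlat = c(-1, 0, 1) * diff(env$lat[1:2]))
  if (!any(is_land(env, rookery[1] + near$dlon, rookery[2] + near$dlat)))
    warning("rookery is not on or adjacent to a land cell")
  seeds <- split_seed(seed, n_individuals)
  meanlog <- log(step_km_mean^2 / sqrt(step_km_mean^2 + step_km_sd^2))
  sdlog <- sqrt(log(1 + step_km_sd^2 / step_km_mean^2))

  tracks <- vector("list", n_individuals)
  for (a in seq_len(n_individuals)) {
    set.seed(seeds[a])
    id <- sprintf("ind%02d", a)
    t0 <- as.POSIXct(paste(env$time[1] + ((a - 1) %% 3), "00:00:00"),
                     tz = "UTC")
    dt_h <- 24 / steps_per_day
    durs <- draw_trip_duration(trips_per_individual)
    ts <- list(); lon <- list(); lat <- list()
    now <- t0
    add_haulout <- function(now, days) {
      n <- days * steps_per_day
      list(ts = now + (seq_len(n) - 1) * dt_h * 3600,
           lon = rep(rookery[1], n), lat = rep(rookery[2], n),
           next_t = now + n * dt_h * 3600)
    }
    h <- add_haulout(now, haulout_days)
    ts[[length(ts) + 1]] <- h$ts; lon[[length(lon) + 1]] <- h$lon
    lat[[length(lat) + 1]] <- h$lat; now <- h$next_t
    for (tr in seq_len(trips_per_individual)) {
      n_steps <- durs[tr] * steps_per_day
      plon <- numeric(n_steps); plat <- numeric(n_steps)
      pos <- rookery
      # commute target: preference-weighted foraging patch within reach
      reach_km <- 0.45 * step_km_mean * n_steps / 2
      t_start <- min(max(as.Date(now, tz = "UTC"), min(env$time)),
                     max(env$time))
      dest <- sample_destination(env, truth, rookery, reach_km, t_start)
      for (i in seq_len(n_steps)) {
        date <- as.Date(now + (i - 1) * dt_h * 3600, tz = "UTC")
        date <- min(max(date, min(env$time)), max(env$time))
        step <- stats::rlnorm(1, meanlog, sdlog)
        progress <- (i - n_steps / 2) / (n_steps / 2)
        # outbound/foraging: drift toward the chosen patch, strong while
        # commuting and weak once on site; return: homeward pull ramps up
        # over the last third of the trip
        if (progress > 0.5) {
          target <- rookery
          drift <- 5 * (progress - 0.5) / 0.5
        } else {
          target <- if (is.null(dest)) rookery else dest
          d_target <- great_circle_km(pos, target)
          # fast commute while far from the patch, loose milling on site
          drift <- if (is.null(dest)) 0 else 6 * min(1, d_target / 30)
        }
        d_home <- great_circle_km(pos, rookery)
        if (i > 0.9 * n_steps && d_home <= 1.5 * step) {
          # close enough on the final leg: walk straight home
          stp <- min(step, d_home)
          pos <- as.numeric(destination_point(
            pos, initial_bearing_deg(pos, rookery), stp))
        } else {
          nxt <- choose_next(env, truth, pos, date, step,
                             homeward = target, drift_strength = drift,
                             exclude_km = 7)
          if (!is.null(nxt)) pos <- as.numeric(nxt)
        }
        plon[i] <- pos[1]; plat[i] <- pos[2]
      }
      # trip always terminates at the rookery
      plon[n_steps] <- rookery[1]; plat[n_steps] <- rookery[2]
      ts[[length(ts) + 1]] <- now + (seq_len(n_steps) - 1) * dt_h * 3600
      lon[[length(lon) + 1]] <- plon; lat[[length(lat) + 1]] <- plat
      now <- now + n_steps * dt_h * 3600
      h <- add_haulout(now, haulout_days)
      ts[[length(ts) + 1]] <- h$ts; lon[[length(lon) + 1]] <- h$lon
      lat[[length(lat) + 1]] <- h$lat; now <- h$next_t
    }
    tracks[[a]] <- data.frame(
      animal_id = id,
      timestamp = as.POSIXct(unlist(lapply(ts, as.numeric)),
                             origin = "1970-01-01", tz = "UTC"),
      lon = unlist(lon), lat = unlist(lat), lc = NA_character_,
      stringsAsFactors = FALSE)
  }
  names(tracks) <- vapply(tracks, function(x) x$animal_id[1], "")
  structure(tracks, class = "raw_tracks")
}
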