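# Correlated-random-walk null model. For each trip phase we extract the
# observed step-length / turning-angle series, simulate null trajectories
# that keep the step lengths and durations but redraw turning angles from
# a wrapped normal fitted to the phase, score each null with the
# trip-similarity weight
#
#   weight = 2 * (d_track - d_crw) / d_track + |angle_track - angle_crw| / 90
#
# (net-displacement distance term plus bearing difference wrapped into
# [0, 180] degrees), and retain nulls below the per-trip upper weight
# quartile that never crossed land.

#' Observed step series of a trip phase
#'
#' Step lengths are consecutive great-circle distances, headings are
#' initial bearings, and turning angles are wrapped heading differences in
#' (-180, 180] (negative = left turn).
#'
#' @param phase A `trip_phase` (or any object with a `positions`
#'   data.frame of `date`, `lon`, `lat`); >= 2 positions required.
#' @return List of class `step_series`: `step_km`, `heading_deg`,
#'   `turn_deg` (length `n_steps - 1`), `start`, `dates`.
#' @export
observed_steps <- function(phase) {
  pos <- phase$positions
  if (is.null(pos) || nrow(pos) < 2) stop("phase needs >= 2 positions")
  p <- cbind(pos$lon, pos$lat)
  n <- nrow(p)
  a <- p[-n, , drop = FALSE]; b <- p[-1, , drop = FALSE]
  step_km <- great_circle_km(a, b)
  heading <- initial_bearing_deg(a, b)
  turn <- if (n > 2) wrap_angle_deg(diff(heading)) else numeric(0)
  structure(list(step_km = step_km, heading_deg = heading, turn_deg = turn,
                 start = as.numeric(p[1, ]), dates = pos$date),
            class = "step_series")
}

# circular mean (deg) and circular SD (deg, via sqrt(-2 log Rbar)) of angles
circular_stats <- function(deg) {
  if (length(deg) == 0) return(list(mu = 0, sd = 0))
  r <- deg * pi / 180
  s <- mean(sin(r)); c <- mean(cos(r))
  rbar <- sqrt(s^2 + c^2)
  sd <- if (rbar >= 1 - 1e-12) 0 else sqrt(-2 * log(rbar)) * 180 / pi
  list(mu = atan2(s, c) * 180 / pi, sd = sd)
}

#' Simulate correlated-random-walk null trajectories for a trip phase
#'
#' Each simulation starts at the phase's first position and replays the
#' observed step-length sequence (and per-step durations) exactly; the
#' initial heading is uniform and each subsequent heading turns by an
#' angle drawn from a wrapped normal with the circular mean and SD of the
#' phase's observed turning angles. A step landing on a land cell is
#' resampled — a replacement step length drawn with replacement from the
#' phase's step-length pool plus a fresh angle — up to `max_retries`
#' times, after which the simulation restarts from scratch (up to
#' `max_restarts`); a simulation still crossing land is flagged.
#'
#' @param phase A `trip_phase` with >= 2 positions.
#' @param env `env_fields` land mask (or `NULL` for open ocean).
#' @param n_sims Number of simulations (>= 10 in production; smaller
#'   values allowed for testing).
#' @param seed Integer seed.
#' @param max_retries,max_restarts Land-rejection limits.
#' @return List of `crw_sim` objects: `positions` (date, lon, lat — same
#'   count as the phase), `land_violation`, `weight` (`NA` until scored).
#' @export
simulate_crw <- function(phase, env = NULL, n_sims = 10, seed = 1L,
                         max_retries = 100, max_restarts = 20) {
  ss <- observed_steps(phase)
  if (!is.null(env) && is_land(env, ss$start[1], ss$start[2]))
    stop("phase start position is on land")
  ang <- circular_stats(ss$turn_deg)
  n_steps <- length(ss$step_km)
  seeds <- split_seed(seed, n_sims)
  on_land <- function(lon, lat)
    if (is.null(env)) FALSE else is_land(env, lon, lat)
  sims <- vector("list", n_sims)
  for (s in seq_len(n_sims)) {
    set.seed(seeds[s])
    violation <- TRUE
    for (attempt in seq_len(max_restarts)) {
      lon <- numeric(n_steps + 1); lat <- numeric(n_steps + 1)
      lon[1] <- ss$start[1]; lat[1] <- ss$start[2]
      heading <- stats::runif(1, 0, 360)
      ok <- TRUE
      for (i in seq_len(n_steps)) {
        step <- ss$step_km[i]
        turn <- if (i == 1) 0 else {
          if (ang$sd == 0) ang$mu
          else wrap_angle_deg(stats::rnorm(1, ang$mu, ang$sd))
        }
        heading <- (heading + turn) %% 360
        nxt <- destination_point(c(lon[i], lat[i]), heading, step)
        tries <- 0
        while (on_land(nxt[1], nxt[2]) && tries < max_retries) {
          step <- sample(ss$step_km, 1, replace = TRUE)
          heading <- stats::runif(1, 0, 360)
          nxt <- destination_point(c(lon[i], lat[i]), heading, step)
          tries <- tries + 1
        }
        if (on_land(nxt[1], nxt[2])) { ok <- FALSE; break }
        lon[i + 1] <- nxt[1]; lat[i + 1] <- nxt[2]
      }
      if (ok) { violation <- FALSE; break }
    }
    sims[[s]] <- structure(list(
      trip_id = phase$trip_id, phase = phase$phase, sim_id = s,
      positions = data.frame(date = ss$dates, lon = lon, lat = lat),
      land_violation = violation, weight = NA_real_), class = "crw_sim")
  }
  sims
}

#' Net displacement of a trajectory
#'
#' Great-circle distance and initial bearing from the first to the last
#' position. A zero displacement has bearing 0 by convention.
#'
#' @param positions Data frame with `lon`, `lat` (>= 2 rows).
#' @return List of class `net_displacement`: `distance_km`, `bearing_deg`.
#' @export
net_displacement <- function(positions) {
  stopifnot(nrow(positions) >= 2)
  a <- c(positions$lon[1], positions$lat[1])
  b <- c(positions$lon[nrow(positions)], positions$lat[nrow(positions)])
  d <- great_circle_km(a, b)
  structure(list(distance_km = d,
                 bearing_deg = if (d == 0) 0 else initial_bearing_deg(a, b)),
            class = "net_displacement")
}

#' Trip-similarity weight of a null trajectory
#'
#' `weight = 2 * (d_track - d_sim) / d_track + delta / 90`, where `delta`
#' is the absolute difference of the two net-displacement bearings wrapped
#' into `[0, 180]` degrees. Higher weights mean a more dissimilar null.
#' The default binds the leading factor 2 to the distance term only and
#' keeps the distance difference signed, as printed in the source formula;
#' `scale_whole_sum` and `absolute_distance` expose the two alternative
#' readings.
#'
#' @param track_nd,sim_nd [net_displacement()] of the observed phase and
#'   of the simulation.
#' @param scale_whole_sum If `TRUE`, multiply the whole sum (not just the
#'   distance term) by 2.
#' @param absolute_distance If `TRUE`, use `|d_track - d_sim|`.
#' @return Numeric weight (0 for identical displacements).
#' @export
crw_weight <- function(track_nd, sim_nd,
                       scale_whole_sum = FALSE, absolute_distance = FALSE) {
  d_track <- track_nd$distance_km
  if (d_track <= 0) stop("degenerate trip: track net displacement is 0")
  dd <- d_track - sim_nd$distance_km
  if (absolute_distance) dd <- abs(dd)
  delta <- bearing_diff_deg(track_nd$bearing_deg, sim_nd$bearing_deg)
  if (scale_whole_sum) 2 * (dd / d_track + delta / 90)
  else 2 * dd / d_track + delta / 90
}

# score a list of sims against their source phase
score_sims <- function(sims, phase) {
  track_nd <- net_displacement(phase$positions)
  lapply(sims, function(s) {
    s$weight <- crw_weight(track_nd, net_displacement(s$positions))
    s
  })
}

#' Filter scored simulations
#'
#' Drops land-violating simulations, then — among the remainder — those
#' with weight strictly above the 75th percentile (linear-interpolation
#' quantile) of the trip's own simulation set.
#'
#' @param sims List of scored `crw_sim` objects.
#' @return The retained simulations (>= 1, else an error suggesting more
#'   simulations).
#' @export
filter_sims <- function(sims) {
  scored <- vapply(sims, function(s) !is.na(s$weight), TRUE)
  if (!all(scored)) stop("all simulations must be scored before filtering")
  clean <- Filter(function(s) !s$land_violation, sims)
  if (length(clean) == 0)
    stop("all simulations removed (land violations); simulate more")
  w <- vapply(clean, function(s) s$weight, 0)
  q75 <- stats::quantile(w, 0.75, type = 7, names = FALSE)
  kept <- clean[w <= q75]
  if (length(kept) == 0)
    stop("all simulations removed by the quartile rule; simulate more")
  kept
}

#' Select one retained simulation as the trip's pseudoabsence
#'
#' @param retained Non-empty list of retained `crw_sim` objects.
#' @param seed Integer seed (uniform, deterministic selection).
#' @return One `crw_sim`.
#' @export
select_pseudoabsence <- function(retained, seed = 1L) {
  if (length(retained) == 0) stop("no retained simulations to select from")
  set.seed(as.integer(seed))
  retained[[sample.int(length(retained), 1)]]
}

#' Simulate, score and filter CRWs for a whole trip
#'
#' Runs the null model per phase (outgoing and incoming), scores each
#' phase's simulations against its own net displacement, filters each
#' phase set by the land and upper-quartile rules, and pairs retained
#' outgoing/incoming simulations index-wise into full null trips (the
#' incoming simulation's duplicated first position is dropped on
#' concatenation so a paired null has exactly the trip's position count).
#'
#' @param trip A `trip` object.
#' @param env `env_fields` land mask.
#' @param n_sims Simulations per phase (>= 10 recommended).
#' @param seed Integer seed.
#' @return List with `phases` (per-phase retained sims), `weights`
#'   (data.frame of all scored sims) and `paired` (list of full null-trip
#'   position data.frames, one per retained pair).
#' @export
crw_null_for_trip <- function(trip, env = NULL, n_sims = 10, seed = 1L) {
  phases <- split_phases(trip)
  phases <- Filter(function(ph) nrow(ph$positions) >= 2, phases)
  seeds <- split_seed(seed, length(phases))
  res <- list(); wtab <- list()
  for (k in seq_along(phases)) {
    ph <- phases[[k]]
    sims <- score_sims(simulate_crw(ph, env, n_sims, seeds[k]), ph)
    kept <- filter_sims(sims)
    res[[ph$phase]] <- kept
    wtab[[k]] <- data.frame(
      trip_id = trip$trip_id, phase = ph$phase,
      sim_id = vapply(sims, function(s) s$sim_id, 0L),
      weight = vapply(sims, function(s) s$weight, 0),
      land_violation = vapply(sims, function(s) s$land_violation, TRUE),
      retained = vapply(sims, function(s)
        any(vapply(kept, function(kk) kk$sim_id == s$sim_id, TRUE)), TRUE))
  }
  paired <- list()
  if (length(res) == 2) {
    n_pair <- min(length(res[[1]]), length(res[[2]]))
    for (j in seq_len(n_pair)) {
      outp <- res[["outgoing"]][[j]]$positions
      inp <- res[["incoming"]][[j]]$positions
      paired[[j]] <- rbind(outp, inp[-1, , drop = FALSE])
    }
  } else if (length(res) == 1) {
    paired <- lapply(res[[1]], function(s) s$positions)
  }
  list(phases = res, weights = do.call(rbind, wtab), paired = paired)
}
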