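# Track regularization, trip segmentation, phase splitting, trip metrics
# and kernel utilization distributions.

#' Iterative speed filter
#'
#' Removes positions that imply sustained travel above `vmax` against every
#' remaining neighbour (both neighbours for interior positions, the single
#' neighbour for the final position). The first position anchors the track
#' and is never removed. One position — the worst offender — is removed per
#' pass until no violations remain.
#'
#' @param track Data frame with `timestamp` (POSIXct), `lon`, `lat`.
#' @param vmax Maximum plausible sustained speed, m/s (default 3, a
#'   swimming otariid).
#' @return The filtered track, order preserved.
#' @export
speed_filter <- function(track, vmax = 3) {
  stopifnot(nrow(track) >= 2)
  repeat {
    n <- nrow(track)
    if (n < 2) break
    p <- cbind(track$lon, track$lat)
    d_m <- great_circle_km(p[-n, , drop = FALSE], p[-1, , drop = FALSE]) * 1000
    dt_s <- diff(as.numeric(track$timestamp))
    sp <- d_m / pmax(dt_s, 1e-9)
    sev_mid <- rep(-Inf, n); sev_end <- -Inf
    for (k in 2:n) {
      prev_fast <- sp[k - 1] > vmax
      if (k < n) {
        if (prev_fast && sp[k] > vmax) sev_mid[k] <- min(sp[k - 1], sp[k])
      } else if (prev_fast) sev_end <- sp[k - 1]
    }
    # interior double-violators (spikes) are removed before a fast tail
    if (any(is.finite(sev_mid))) {
      track <- track[-which.max(sev_mid), , drop = FALSE]
    } else if (is.finite(sev_end)) {
      track <- track[-n, , drop = FALSE]
    } else break
  }
  track
}

#' Regularize a track to one position per day
#'
#' Linear interpolation of longitude and latitude in time at fixed daily
#' epochs (00:00 UTC). A day is kept only when bracketing observations
#' exist within `gap_max_days` of each other; interpolated positions on
#' land (against `env`'s bathymetry mask, when given) are removed.
#'
#' @param track Data frame with `timestamp` (POSIXct) or `date` column,
#'   plus `lon`, `lat`, and optionally `animal_id`.
#' @param env Optional `env_fields` providing the land mask.
#' @param gap_max_days Maximum bracketing-observation gap to interpolate
#'   across (default 3 days).
#' @return Data frame with `animal_id`, `date`, `lon`, `lat`; one row per
#'   retained day.
#' @export
regularize_daily <- function(track, env = NULL, gap_max_days = 3) {
  if (!"timestamp" %in% names(track) && "date" %in% names(track))
    track$timestamp <- as.POSIXct(paste(track$date, "00:00:00"), tz = "UTC")
  stopifnot(nrow(track) >= 2)
  tt <- as.numeric(track$timestamp)
  o <- order(tt); tt <- tt[o]
  lon <- track$lon[o]; lat <- track$lat[o]
  day0 <- as.numeric(as.POSIXct(
    paste(as.Date(track$timestamp[o][1], tz = "UTC"), "00:00:00"), tz = "UTC"))
  if (day0 < tt[1]) day0 <- day0 + 86400
  epochs <- seq(day0, tt[length(tt)], by = 86400)
  keep <- logical(length(epochs))
  elon <- numeric(length(epochs)); elat <- numeric(length(epochs))
  for (k in seq_along(epochs)) {
    e <- epochs[k]
    i_prev <- max(which(tt <= e))
    i_next <- min(which(tt >= e))
    if (tt[i_next] - tt[i_prev] > gap_max_days * 86400) next
    if (i_prev == i_next) {
      elon[k] <- lon[i_prev]; elat[k] <- lat[i_prev]
    } else {
      w <- (e - tt[i_prev]) / (tt[i_next] - tt[i_prev])
      elon[k] <- lon[i_prev] + w * (lon[i_next] - lon[i_prev])
      elat[k] <- lat[i_prev] + w * (lat[i_next] - lat[i_prev])
    }
    keep[k] <- TRUE
  }
  out <- data.frame(
    animal_id = if ("animal_id" %in% names(track)) track$animal_id[1] else NA,
    date = as.Date(as.POSIXct(epochs, origin = "1970-01-01", tz = "UTC"),
                   tz = "UTC"),
    lon = elon, lat = elat)[keep, , drop = FALSE]
  if (!is.null(env)) out <- out[!is_land(env, out$lon, out$lat), , drop = FALSE]
  if (nrow(out) == 0) stop("no usable daily positions after regularization")
  rownames(out) <- NULL
  out
}

#' Segment a daily track into foraging trips
#'
#' Daily positions within `haulout_radius_km` of the colony (or on land)
#' are haul-out states; maximal runs of at-sea states bounded by haul-out
#' states on both sides become trips. Runs touching the start or end of
#' the track without a bounding haul-out are discarded as incomplete.
#'
#' @param daily Data frame from [regularize_daily()].
#' @param colony `c(lon, lat)` of the rookery.
#' @param haulout_radius_km Haul-out detection radius (default 5 km).
#' @param env Optional `env_fields` land mask.
#' @return List of `trip` objects (possibly empty), each with `trip_id`,
#'   `animal_id`, `colony`, and a `positions` data.frame (date, lon, lat).
#' @export
segment_trips <- function(daily, colony, haulout_radius_km = 5, env = NULL) {
  d_col <- great_circle_km(cbind(daily$lon, daily$lat),
                           matrix(colony, nrow(daily), 2, byrow = TRUE))
  haul <- d_col <= haulout_radius_km
  if (!is.null(env)) haul <- haul | is_land(env, daily$lon, daily$lat)
  r <- rle(haul)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  trips <- list()
  for (b in seq_along(r$values)) {
    if (r$values[b]) next
    if (b == 1 || b == length(r$values)) next  # incomplete run
    pos <- daily[starts[b]:ends[b], , drop = FALSE]
    trips[[length(trips) + 1]] <- structure(list(
      trip_id = sprintf("%s_t%02d", daily$animal_id[1], length(trips) + 1),
      animal_id = daily$animal_id[1], colony = colony,
      positions = pos,
      start_date = min(pos$date), end_date = max(pos$date)), class = "trip")
  }
  trips
}

#' Split a trip into outgoing and incoming phases at the apex
#'
#' The apex is the position of maximum great-circle distance from the
#' colony (earliest index on ties). Both phases share the apex position.
#'
#' @param trip A `trip` object with >= 2 positions.
#' @return List of two `trip_phase` objects (`phase` = "outgoing",
#'   "incoming").
#' @export
split_phases <- function(trip) {
  pos <- trip$positions
  stopifnot(nrow(pos) >= 2)
  d <- great_circle_km(cbind(pos$lon, pos$lat),
                       matrix(trip$colony, nrow(pos), 2, byrow = TRUE))
  apex <- which.max(d)  # earliest on ties
  mk <- function(rows, phase) structure(list(
    trip_id = trip$trip_id, animal_id = trip$animal_id, phase = phase,
    colony = trip$colony, positions = pos[rows, , drop = FALSE]),
    class = "trip_phase")
  list(mk(1:apex, "outgoing"), mk(apex:nrow(pos), "incoming"))
}

#' Trip metrics
#'
#' @param trip A `trip` object.
#' @return List: `duration_days` (number of daily at-sea positions),
#'   `max_distance_km` (farthest position from colony),
#'   `total_distance_km` (summed consecutive step lengths).
#' @export
trip_metrics <- function(trip) {
  pos <- trip$positions
  p <- cbind(pos$lon, pos$lat)
  d_col <- great_circle_km(p, matrix(trip$colony, nrow(p), 2, byrow = TRUE))
  steps <- if (nrow(p) > 1)
    great_circle_km(p[-nrow(p), , drop = FALSE], p[-1, , drop = FALSE]) else 0
  list(duration_days = nrow(pos),
       max_distance_km = max(d_col),
       total_distance_km = sum(steps))
}

#' Kernel utilization distribution
#'
#' Bivariate Gaussian kernel density of at-sea positions on a planar
#' equirectangular projection about the points' centroid, with the
#' ad-hoc reference ("href") bandwidth
#' \eqn{h = 0.5 (s_x + s_y) n^{-1/6}}. Contour levels are the smallest
#' regions containing the stated probability mass.
#'
#' @param lon,lat At-sea positions (>= 5 points).
#' @param levels Probability levels (default `c(0.5, 0.95)`).
#' @param grid_n Density grid size per axis.
#' @return Object of class `utilization_distribution`: density grid,
#'   probability mass per cell, per-level density thresholds, contour
#'   polygons in lon/lat, per-level areas (km^2) and bandwidth (km).
#' @export
kernel_ud <- function(lon, lat, levels = c(0.5, 0.95), grid_n = 128) {
  n <- length(lon)
  if (n < 5) stop("kernel_ud needs at least 5 points")
  lon0 <- mean(lon); lat0 <- mean(lat)
  x <- (lon - lon0) * 111.19 * cos(lat0 * pi / 180)
  y <- (lat - lat0) * 111.19
  h <- 0.5 * (stats::sd(x) + stats::sd(y)) * n^(-1 / 6)
  if (h <= 0) h <- 1
  pad <- 4 * h
  kd <- MASS::kde2d(x, y, h = 4 * h, n = grid_n,
                    lims = c(range(x) + c(-pad, pad), range(y) + c(-pad, pad)))
  dx <- diff(kd$x[1:2]); dy <- diff(kd$y[1:2])
  mass <- kd$z * dx * dy
  mass <- mass / sum(mass)
  ord <- order(kd$z, decreasing = TRUE)
  cum <- cumsum(mass[ord])
  thr <- vapply(levels, function(p) kd$z[ord][min(which(cum >= p))], 0)
  areas <- vapply(thr, function(z0) sum(kd$z >= z0) * dx * dy, 0)
  contours <- lapply(thr, function(z0) {
    cl <- grDevices::contourLines(kd$x, kd$y, kd$z, levels = z0)
    lapply(cl, function(cc) data.frame(
      lon = lon0 + cc$x / (111.19 * cos(lat0 * pi / 180)),
      lat = lat0 + cc$y / 111.19))
  })
  names(contours) <- names(areas) <- paste0(levels * 100, "%")
  structure(list(x = kd$x, y = kd$y, z = kd$z, mass = mass,
                 center = c(lon = lon0, lat = lat0), bandwidth_km = h,
                 levels = levels, thresholds = thr, areas_km2 = areas,
                 contours = contours),
            class = "utilization_distribution")
}

#' Summarize the packaged trip-metrics fixture
#'
#' Computes per-column count, mean, sample SD, min and max for trip
#' duration, maximum distance from colony and total trip distance, plus
#' trip counts by tagging location, from a 72-trip reference table.
#'
#' @param fixture Data frame with columns `tag_id`, `location`,
#'   `start_date`, `end_date`, `duration_days`, `max_distance_km`,
#'   `total_distance_km`. Defaults to the packaged fixture.
#' @return List with `stats` (data.frame, one row per metric) and
#'   `location_counts` (named integer vector).
#' @export
table1_summary <- function(fixture = table1_fixture()) {
  need <- c("tag_id", "location", "start_date", "end_date",
            "duration_days", "max_distance_km", "total_distance_km")
  if (!all(need %in% names(fixture)))
    stop("malformed fixture: expected columns ", paste(need, collapse = ", "))
  num <- c("duration_days", "max_distance_km", "total_distance_km")
  stats_df <- do.call(rbind, lapply(num, function(v) {
    x <- as.numeric(fixture[[v]])
    if (any(is.na(x))) stop("malformed fixture: non-numeric ", v)
    data.frame(metric = v, n = length(x), mean = mean(x),
               sd = stats::sd(x), min = min(x), max = max(x))
  }))
  list(stats = stats_df,
       location_counts = c(table(fixture$location)))
}

#' Load the packaged 72-trip reference table
#' @return Data frame of 72 foraging trips (tag id, tagging location,
#'   dates, duration, maximum and total distance).
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_fixture.csv", package = "crwhabitat",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
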