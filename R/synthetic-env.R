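# Synthetic environmental scenario: a winter eastern-boundary-upwelling
# domain with a straight meridional coastline (land to the east), an
# analytic shelf-to-abyss bathymetry, a cool upwelled SST band inshore,
# chlorophyll anticorrelated with SST, and a sea-level-anomaly field made
# of drifting Gaussian mesoscale eddies whose spatial derivatives give
# geostrophic currents (hence rotational flow and positive EKE).

#' Define a synthetic environmental scenario
#'
#' Parameters describe a California Current-like winter domain used to
#' exercise the pipeline with known ground truth.
#'
#' @param lon_range,lat_range Numeric length-2, degrees east / north.
#' @param grid_step Grid spacing in degrees (> 0).
#' @param date_range Length-2 `Date` (or coercible) pair spanning >= 1 day.
#' @param coast_lon Longitude of the straight meridional coastline; cells at
#'   or east of it are land. Defaults to 1 degree inside the eastern edge.
#' @param island Optional `c(lon, lat)`: a single-cell offshore island
#'   (a rookery site, emulating an offshore breeding colony) added to the
#'   land mask at the nearest grid cell.
#' @param n_eddies Number of Gaussian sea-level-anomaly eddies (>= 0).
#' @param eddy_amplitude Typical eddy amplitude, cm.
#' @param sst_inshore,sst_offshore Asymptotic SST at the coast and in the
#'   far field, deg C. All noise-free SST values lie between them.
#' @param chl_sst_slope Slope of log10 chlorophyll-a per deg C of SST
#'   (negative: cool water is greener).
#' @param chl_offshore_log10 log10 chlorophyll-a (mg/m^3) at `sst_offshore`.
#' @param wind_v_mean Mean meridional wind, m/s (negative = equatorward,
#'   upwelling-favourable).
#' @param noise_sd Named list of additive noise SDs:
#'   `sst` (deg C), `chl_log10`, `sla` (cm), `wind_v` (m/s). All >= 0.
#' @param seed Integer seed; the whole field set is deterministic given it.
#' @return An object of class `env_scenario`.
#' @export
env_scenario <- function(lon_range = c(-127, -118.5),
                         lat_range = c(30, 38),
                         grid_step = 0.25,
                         date_range = as.Date(c("2006-11-01", "2006-12-31")),
                         coast_lon = NULL,
                         island = NULL,
                         n_eddies = 6,
                         eddy_amplitude = 8,
                         sst_inshore = 12,
                         sst_offshore = 18,
                         chl_sst_slope = -0.15,
                         chl_offshore_log10 = -0.3,
                         wind_v_mean = -3,
                         noise_sd = list(sst = 0.3, chl_log10 = 0.1,
                                         sla = 0.5, wind_v = 1),
                         seed = 1L) {
  date_range <- as.Date(date_range)
  if (grid_step <= 0) stop("grid_step must be > 0")
  if (diff(lon_range) <= 0 || diff(lat_range) <= 0)
    stop("degenerate lon/lat range")
  if (diff(as.numeric(date_range)) < 1) stop("date_range must span >= 1 day")
  if (n_eddies < 0) stop("n_eddies must be >= 0")
  defaults <- list(sst = 0, chl_log10 = 0, sla = 0, wind_v = 0)
  noise_sd <- utils::modifyList(defaults, as.list(noise_sd))
  if (any(unlist(noise_sd) < 0)) stop("noise SDs must be >= 0")
  if (is.null(coast_lon)) coast_lon <- lon_range[2] - 1
  structure(list(lon_range = lon_range, lat_range = lat_range,
                 grid_step = grid_step, date_range = date_range,
                 coast_lon = coast_lon, island = island,
                 n_eddies = n_eddies,
                 eddy_amplitude = eddy_amplitude,
                 sst_inshore = sst_inshore, sst_offshore = sst_offshore,
                 chl_sst_slope = chl_sst_slope,
                 chl_offshore_log10 = chl_offshore_log10,
                 wind_v_mean = wind_v_mean,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "env_scenario")
}

# signed distance (km) west of the coastline at each (lon, lat);
# positive at sea, negative over land
coast_distance_km <- function(lon, lat, coast_lon) {
  (coast_lon - lon) * 111.19 * cos(lat * pi / 180)
}

# 3x3-neighbourhood sample SD of a matrix (NA-padded edges use the
# available neighbours); used for roughness / mesoscale-variability layers
local_sd <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  s <- matrix(0, nr, nc); s2 <- matrix(0, nr, nc); n <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    ri <- max(1, 1 + di):min(nr, nr + di)
    rj <- max(1, 1 + dj):min(nc, nc + dj)
    si <- ri - di; sj <- rj - dj
    v <- m[si, sj, drop = FALSE]
    s[ri, rj] <- s[ri, rj] + v
    s2[ri, rj] <- s2[ri, rj] + v^2
    n[ri, rj] <- n[ri, rj] + 1
  }
  out <- (s2 - s^2 / n) / (n - 1)
  out[out < 0] <- 0
  sqrt(out)
}

#' Generate a gridded synthetic environmental field set
#'
#' Produces daily SST, chlorophyll-a, SLA, geostrophic u/v, meridional wind
#' and derived SST SD / SLA SD layers plus static bathymetry and bathymetry
#' SD on the scenario grid. Bathymetry is negative metres below sea level,
#' monotone non-increasing with distance from the coast; cells at or east
#' of the coastline have elevation >= 0 and form the land mask. SLA is a
#' superposition of `n_eddies` drifting Gaussian anomalies; u and v are the
#' geostrophic velocities implied by the anomaly's spatial gradient, so the
#' flow is rotational and EKE is zero only where the anomaly gradient
#' vanishes. Deterministic under the scenario seed.
#'
#' @param scenario An [env_scenario()].
#' @return Object of class `env_fields`: grid vectors `lon`, `lat`, `time`
#'   (Date), dynamic variables as `[lon, lat, time]` arrays in `$vars`
#'   (sst deg C, chl mg/m^3, sla cm, u/v cm/s, wind_v m/s, sst_sd deg C,
#'   sla_sd cm), and static `[lon, lat]` matrices in `$static`
#'   (bathymetry m, bathymetry_sd m).
#' @export
generate_env_fields <- function(scenario) {
  stopifnot(inherits(scenario, "env_scenario"))
  sc <- scenario
  lon <- seq(sc$lon_range[1], sc$lon_range[2], by = sc$grid_step)
  lat <- seq(sc$lat_range[1], sc$lat_range[2], by = sc$grid_step)
  if (length(lon) < 2 || length(lat) < 2) stop("degenerate grid")
  time <- seq(sc$date_range[1], sc$date_range[2], by = "day")
  nlon <- length(lon); nlat <- length(lat); nt <- length(time)

  seeds <- split_seed(sc$seed, 4)

  d_km <- outer(lon, lat, function(x, y) coast_distance_km(x, y, sc$coast_lon))

  # analytic shelf: exponential approach to a 4000 m abyss; land +50 m
  bathy <- ifelse(d_km <= 0, 50, -4000 * (1 - exp(-d_km / 60)))
  if (!is.null(sc$island)) {
    ii <- round((sc$island[1] - lon[1]) / sc$grid_step) + 1
    jj <- round((sc$island[2] - lat[1]) / sc$grid_step) + 1
    if (ii < 1 || ii > nlon || jj < 1 || jj > nlat)
      stop("island outside grid")
    bathy[ii, jj] <- 20
  }
  bathy_sd <- local_sd(bathy)

  # SST: convex combination of inshore and offshore endmembers. The weight
  # decays offshore, carries along-shore upwelling filaments whose phase
  # drifts through the season (cool patches move, so SST is not a pure
  # function of depth), and is gently modulated seasonally.
  set.seed(seeds[1])
  t_idx <- seq_len(nt)
  sst <- array(0, c(nlon, nlat, nt))
  chl <- array(0, c(nlon, nlat, nt))
  w0 <- exp(-pmax(d_km, 0) / 120)
  for (k in t_idx) {
    # along-shore filament bands whose amplitude grows offshore (eddy
    # stirring), so the coolest reachable water is not always coastal and
    # SST decorrelates from depth; the phase drifts slowly (persistent
    # within a trip, decorrelating across trips)
    filament <- (0.7 - 0.35 * w0) * outer(rep(1, nlon),
                            0.5 + 0.5 * sin(2 * pi * lat / 2.5 +
                                            2 * pi * k / 270))
    w <- pmin(1, pmax(0, 0.3 * w0 * (1 + 0.15 * sin(2 * pi * k / 60)) +
                        filament))
    s <- sc$sst_inshore * w + sc$sst_offshore * (1 - w)
    if (sc$noise_sd$sst > 0)
      s <- s + matrix(stats::rnorm(nlon * nlat, 0, sc$noise_sd$sst), nlon, nlat)
    sst[, , k] <- s
    lchl <- sc$chl_offshore_log10 + sc$chl_sst_slope * (s - sc$sst_offshore)
    if (sc$noise_sd$chl_log10 > 0)
      lchl <- lchl +
        matrix(stats::rnorm(nlon * nlat, 0, sc$noise_sd$chl_log10), nlon, nlat)
    chl[, , k] <- 10^lchl
  }

  # eddies: Gaussian SLA anomalies drifting slowly westward; u, v are the
  # geostrophic velocities of the noise-free anomaly field
  set.seed(seeds[2])
  sla <- array(0, c(nlon, nlat, nt))
  u <- array(0, c(nlon, nlat, nt))
  v <- array(0, c(nlon, nlat, nt))
  if (sc$n_eddies > 0) {
    amp_cm <- sc$eddy_amplitude * stats::runif(sc$n_eddies, 0.6, 1.4) *
      rep_len(c(1, -1), sc$n_eddies)
    sigma_km <- stats::runif(sc$n_eddies, 40, 80)
    e_lo <- sc$lon_range[1] + 1; e_hi <- sc$coast_lon - 1
    if (e_hi <= e_lo) { e_lo <- sc$lon_range[1]; e_hi <- sc$lon_range[2] }
    a_lo <- sc$lat_range[1] + 1; a_hi <- sc$lat_range[2] - 1
    if (a_hi <= a_lo) { a_lo <- sc$lat_range[1]; a_hi <- sc$lat_range[2] }
    lon0 <- stats::runif(sc$n_eddies, e_lo, e_hi)
    lat0 <- stats::runif(sc$n_eddies, a_lo, a_hi)
    drift_lon <- -1.5 / (111.19 * cos(lat0 * pi / 180))  # deg/day westward
    g <- 9.81
    km_per_deg_lat <- 111.19
    for (k in t_idx) {
      ec_lon <- lon0 + drift_lon * (k - 1)
      ec_lat <- lat0
      eta <- matrix(0, nlon, nlat)
      detadx <- matrix(0, nlon, nlat)  # cm per km
      detady <- matrix(0, nlon, nlat)
      for (e in seq_len(sc$n_eddies)) {
        km_per_deg_lon <- km_per_deg_lat * cos(ec_lat[e] * pi / 180)
        dx <- outer((lon - ec_lon[e]) * km_per_deg_lon, rep(1, nlat))
        dy <- outer(rep(1, nlon), (lat - ec_lat[e]) * km_per_deg_lat)
        g2 <- amp_cm[e] * exp(-(dx^2 + dy^2) / (2 * sigma_km[e]^2))
        eta <- eta + g2
        detadx <- detadx - g2 * dx / sigma_km[e]^2
        detady <- detady - g2 * dy / sigma_km[e]^2
      }
      f <- outer(rep(1, nlon), 2 * 7.2921e-5 * sin(lat * pi / 180))
      # eta in cm, gradient in cm/km -> m/m: /100 (cm->m) /1000 (km->m)
      u[, , k] <- (-g / f) * (detady / 1e5) * 100  # cm/s
      v[, , k] <- (g / f) * (detadx / 1e5) * 100
      if (sc$noise_sd$sla > 0)
        eta <- eta + matrix(stats::rnorm(nlon * nlat, 0, sc$noise_sd$sla),
                            nlon, nlat)
      sla[, , k] <- eta
    }
  }

  set.seed(seeds[3])
  wind_v <- array(0, c(nlon, nlat, nt))
  for (k in t_idx) {
    wv <- sc$wind_v_mean + 2 * sin(2 * pi * k / 45)
    wind_v[, , k] <- wv + if (sc$noise_sd$wind_v > 0)
      matrix(stats::rnorm(nlon * nlat, 0, sc$noise_sd$wind_v), nlon, nlat)
    else 0
  }

  sst_sd <- array(0, c(nlon, nlat, nt))
  sla_sd <- array(0, c(nlon, nlat, nt))
  for (k in t_idx) {
    sst_sd[, , k] <- local_sd(sst[, , k])
    sla_sd[, , k] <- local_sd(sla[, , k])
  }

  structure(list(
    lon = lon, lat = lat, time = time,
    vars = list(sst = sst, chl = chl, sla = sla, u = u, v = v,
                wind_v = wind_v, sst_sd = sst_sd, sla_sd = sla_sd),
    static = list(bathymetry = bathy, bathymetry_sd = bathy_sd),
    scenario = sc), class = "env_fields")
}

#' @export
print.env_fields <- function(x, ...) {
  cat(sprintf(
    "env_fields: %d x %d grid (%.2f deg), %d days (%s to %s), %d dynamic vars\n",
    length(x$lon), length(x$lat), x$scenario$grid_step, length(x$time),
    format(min(x$time)), format(max(x$time)), length(x$vars)))
  invisible(x)
}

# nearest-cell indices; NA outside the grid edges (+ half a step slack)
grid_index <- function(env, lon, lat) {
  step <- diff(env$lon[1:2])
  i <- round((lon - env$lon[1]) / step) + 1
  j <- round((lat - env$lat[1]) / diff(env$lat[1:2])) + 1
  i[i < 1 | i > length(env$lon)] <- NA
  j[j < 1 | j > length(env$lat)] <- NA
  list(i = i, j = j)
}

#' Land test against the field set's bathymetry
#'
#' A position is on land when its nearest grid cell has elevation >= 0.
#' Positions outside the grid are treated as open sea.
#'
#' @param env An `env_fields` object.
#' @param lon,lat Numeric vectors of positions.
#' @return Logical vector.
#' @export
is_land <- function(env, lon, lat) {
  ix <- grid_index(env, lon, lat)
  out <- rep(FALSE, length(lon))
  ok <- !is.na(ix$i) & !is.na(ix$j)
  out[ok] <- env$static$bathymetry[cbind(ix$i[ok], ix$j[ok])] >= 0
  out
}

# nearest-cell raw value of one variable at vectorized (lon, lat) and a
# single date; static layers ignore the date
env_cell_value <- function(env, var, lon, lat, date = NULL) {
  ix <- grid_index(env, lon, lat)
  out <- rep(NA_real_, length(lon))
  ok <- !is.na(ix$i) & !is.na(ix$j)
  if (!any(ok)) return(out)
  if (var %in% names(env$static)) {
    out[ok] <- env$static[[var]][cbind(ix$i[ok], ix$j[ok])]
  } else {
    k <- which.min(abs(as.numeric(as.Date(date)) - as.numeric(env$time)))
    out[ok] <- env$vars[[var]][cbind(ix$i[ok], ix$j[ok], k)]
  }
  out
}
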