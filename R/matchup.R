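# Environmental matchup: join presence and pseudoabsence positions to
# covariates by 1-degree box means, derive EKE from the box-averaged
# geostrophic components, apply the variable transforms, and emit the
# modeling table.

# native temporal resolution (days) of each dynamic variable; the matchup
# uses the nearest time slice within this window
NATIVE_RES_DAYS <- c(sst = 1, chl = 8, sla = 1, u = 1, v = 1,
                     wind_v = 1, sst_sd = 8, sla_sd = 8)

#' Box-mean extraction of one variable
#'
#' Mean over all non-missing grid cells whose centres lie in the half-open
#' box `[lon - b/2, lon + b/2) x [lat - b/2, lat + b/2)`, using the time
#' slice nearest to `date` within the variable's native resolution window
#' (static layers ignore the date). Returns `NA` (with a warning for
#' out-of-window dates) when no valid cell exists.
#'
#' @param env An `env_fields` object.
#' @param var Variable name in `env$vars` or `env$static`.
#' @param lon,lat Box centre, degrees.
#' @param date Date (ignored for static layers).
#' @param box_deg Box edge length, degrees (default 1).
#' @return Scalar mean or `NA`.
#' @export
extract_box_mean <- function(env, var, lon, lat, date = NULL, box_deg = 1.0) {
  half <- box_deg / 2
  ii <- which(env$lon >= lon - half & env$lon < lon + half)
  jj <- which(env$lat >= lat - half & env$lat < lat + half)
  if (length(ii) == 0 || length(jj) == 0) return(NA_real_)
  if (var %in% names(env$static)) {
    vals <- env$static[[var]][ii, jj]
  } else {
    if (is.null(date)) stop("dynamic variable ", var, " needs a date")
    win <- if (var %in% names(NATIVE_RES_DAYS)) NATIVE_RES_DAYS[[var]] else 1
    dt <- abs(as.numeric(as.Date(date)) - as.numeric(env$time))
    if (min(dt) > win) {
      warning(sprintf("%s: date %s outside temporal coverage window (%g d)",
                      var, format(as.Date(date)), win))
      return(NA_real_)
    }
    vals <- env$vars[[var]][ii, jj, which.min(dt)]
  }
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Eddy kinetic energy from current components
#'
#' `EKE = (u^2 + v^2) / 2`, in cm^2/s^2 for u, v in cm/s.
#'
#' @param u,v Zonal and meridional geostrophic components.
#' @return Non-negative EKE, same length as the inputs.
#' @export
compute_eke <- function(u, v) (u^2 + v^2) / 2

#' Apply the variable transforms to a matchup table
#'
#' Chlorophyll-a and EKE are log10-transformed and bathymetry SD is
#' square-root-transformed (the transforms that make the covariates
#' approximately normal); bathymetry remains negative metres below sea
#' level. Records with non-positive chlorophyll or EKE (log domain) are
#' excluded and counted in the `excluded_nonpositive` attribute.
#'
#' @param records Data frame with (at least) `chl`, `eke`,
#'   `bathymetry_sd` columns on the raw scale.
#' @return The table with the three columns replaced by their transformed
#'   values.
#' @export
apply_transforms <- function(records) {
  bad <- (!is.na(records$chl) & records$chl <= 0) |
    (!is.na(records$eke) & records$eke <= 0)
  if (any(bad)) {
    message(sum(bad), " record(s) excluded: non-positive Chl-a or EKE")
    records <- records[!bad, , drop = FALSE]
  }
  records$chl <- log10(records$chl)
  records$eke <- log10(records$eke)
  records$bathymetry_sd <- sqrt(pmax(records$bathymetry_sd, 0))
  attr(records, "excluded_nonpositive") <- sum(bad)
  records
}

MODEL_COVARIATES <- c("sst", "chl", "sla", "sla_sd", "sst_sd", "wind_v",
                      "bathymetry", "bathymetry_sd", "eke")

# raw (untransformed) box-mean covariates for a set of positions
raw_covariates <- function(env, lon, lat, date, box_deg = 1.0) {
  n <- length(lon)
  box_vars <- c("sst", "chl", "sla", "sla_sd", "sst_sd", "wind_v",
                "bathymetry", "bathymetry_sd", "u", "v")
  out <- matrix(NA_real_, n, length(box_vars),
                dimnames = list(NULL, box_vars))
  for (r in seq_len(n)) for (v in box_vars)
    out[r, v] <- extract_box_mean(env, v, lon[r], lat[r], date[r], box_deg)
  df <- as.data.frame(out)
  df$eke <- compute_eke(df$u, df$v)
  df$u <- NULL; df$v <- NULL
  df
}

#' Build the presence/pseudoabsence matchup table
#'
#' One record per daily position. Covariates are 1-degree box means; EKE
#' is computed from the box-averaged geostrophic components and then
#' log-transformed with the other transforms; distance from the colony is
#' the great-circle distance. Records with any missing covariate are
#' excluded and counted; more than 50% exclusions is an error (coverage
#' mismatch between tracks and fields).
#'
#' @param presences,pseudoabsences Data frames with `animal_id`,
#'   `trip_id`, `date`, `lon`, `lat` (daily positions).
#' @param env An `env_fields` object.
#' @param colony `c(lon, lat)`.
#' @param box_deg Matchup box edge, degrees.
#' @return Data frame (`matchup` attribute class) with label column
#'   `source`, position/id columns, the transformed covariates and
#'   `dist_colony_km`; attribute `n_excluded` counts dropped records.
#' @export
build_matchup_table <- function(presences, pseudoabsences, env, colony,
                                box_deg = 1.0) {
  if (!"sim_id" %in% names(presences)) presences$sim_id <- NA_integer_
  if (!"sim_id" %in% names(pseudoabsences))
    pseudoabsences$sim_id <- NA_integer_
  keep_cols <- c("animal_id", "trip_id", "sim_id", "date", "lon", "lat")
  stack <- rbind(cbind(source = "presence", presences[keep_cols]),
                 cbind(source = "pseudoabsence", pseudoabsences[keep_cols]))
  cov <- raw_covariates(env, stack$lon, stack$lat, stack$date, box_deg)
  tab <- cbind(stack, cov)
  tab$dist_colony_km <- great_circle_km(
    cbind(tab$lon, tab$lat), matrix(colony, nrow(tab), 2, byrow = TRUE))
  n0 <- nrow(tab)
  miss <- !stats::complete.cases(tab[MODEL_COVARIATES])
  tab <- tab[!miss, , drop = FALSE]
  tab <- apply_transforms(tab)
  n_excluded <- n0 - nrow(tab)
  if (n_excluded > 0.5 * n0)
    stop("more than 50% of records excluded (", n_excluded, "/", n0,
         "): field coverage does not match the tracks")
  rownames(tab) <- NULL
  attr(tab, "n_excluded") <- n_excluded
  tab
}
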