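# Daily habitat-suitability surfaces on a 0.25-degree grid and seasonal
# mean / standard-error composites.

#' Predict a daily suitability surface
#'
#' Evaluates the fitted model on a regular grid over the field domain.
#' Covariates are extracted at cell centres with the same 1-degree
#' box-mean operator and transforms used in training; the per-individual
#' random intercept is set to its population mean (zero), so surfaces are
#' population-level. Suitability is the predicted occurrence probability,
#' already in `[0, 1]`; `rescale = TRUE` additionally min-max rescales the
#' surface. Land cells and cells with any missing covariate are masked.
#'
#' @param fit A `habitat_fit`.
#' @param env An `env_fields` object.
#' @param date Date within the field coverage.
#' @param grid_step Surface resolution, degrees (default 0.25).
#' @param colony `c(lon, lat)`; required when the model uses
#'   `dist_colony_km`.
#' @param box_deg Covariate box edge, degrees.
#' @param rescale Min-max rescale the unmasked values to `[0, 1]`.
#' @return Object of class `prediction_surface`: `lon`, `lat`, `date`,
#'   `values` matrix `[lon, lat]` with `NA` mask.
#' @export
predict_daily <- function(fit, env, date, grid_step = 0.25, colony = NULL,
                          box_deg = 1.0, rescale = FALSE) {
  stopifnot(inherits(fit, "habitat_fit"))
  date <- as.Date(date)
  lon <- seq(min(env$lon), max(env$lon), by = grid_step)
  lat <- seq(min(env$lat), max(env$lat), by = grid_step)
  g <- expand.grid(lon = lon, lat = lat)
  needs_dist <- "dist_colony_km" %in% fit$covariates
  if (needs_dist && is.null(colony))
    stop("model covariate dist_colony_km needs a colony position")
  cov <- raw_covariates(env, g$lon, g$lat, rep(date, nrow(g)), box_deg)
  bad_log <- (!is.na(cov$chl) & cov$chl <= 0) |
    (!is.na(cov$eke) & cov$eke <= 0)
  cov$chl <- ifelse(cov$chl > 0, log10(cov$chl), NA)
  cov$eke <- ifelse(cov$eke > 0, log10(cov$eke), NA)
  cov$bathymetry_sd <- sqrt(pmax(cov$bathymetry_sd, 0))
  if (needs_dist)
    cov$dist_colony_km <- great_circle_km(
      cbind(g$lon, g$lat), matrix(colony, nrow(g), 2, byrow = TRUE))
  missing_cov <- setdiff(fit$covariates, names(cov))
  if (length(missing_cov) > 0)
    stop("missing covariate layer(s): ", paste(missing_cov, collapse = ", "))
  ok <- stats::complete.cases(cov[fit$covariates]) & !bad_log &
    !is_land(env, g$lon, g$lat)
  p <- rep(NA_real_, nrow(g))
  if (any(ok)) {
    nd <- cov[ok, fit$covariates, drop = FALSE]
    lev <- levels(fit$gam$model$animal_id)
    nd$animal_id <- factor(lev[1], levels = lev)
    p[ok] <- as.numeric(mgcv::predict.gam(
      fit$gam, newdata = nd, type = "response", exclude = "s(animal_id)",
      newdata.guaranteed = TRUE))
  }
  if (rescale && any(ok)) {
    rng <- range(p[ok])
    if (diff(rng) > 0) p[ok] <- (p[ok] - rng[1]) / diff(rng)
  }
  structure(list(lon = lon, lat = lat, date = date,
                 grid_step = grid_step,
                 values = matrix(p, length(lon), length(lat))),
            class = "prediction_surface")
}

#' Composite daily surfaces into seasonal mean and SE maps
#'
#' Cellwise mean over unmasked days and standard error
#' (sample SD / sqrt(n_days)); cells unmasked on fewer than one day stay
#' masked, and single-day cells get SE 0.
#'
#' @param surfaces List of >= 2 `prediction_surface` objects on one grid.
#' @return Object of class `seasonal_composite`: `mean`, `se`, `n_days`
#'   matrices plus the grid vectors.
#' @export
seasonal_composite <- function(surfaces) {
  stopifnot(length(surfaces) >= 2)
  ref <- surfaces[[1]]
  for (s in surfaces[-1])
    if (!identical(s$lon, ref$lon) || !identical(s$lat, ref$lat))
      stop("surfaces are not on identical grids")
  arr <- simplify2array(lapply(surfaces, function(s) s$values))
  n <- apply(!is.na(arr), c(1, 2), sum)
  mu <- apply(arr, c(1, 2), function(x) mean(x, na.rm = TRUE))
  sdv <- apply(arr, c(1, 2), function(x) stats::sd(x, na.rm = TRUE))
  se <- ifelse(n > 1, sdv / sqrt(n), ifelse(n == 1, 0, NA))
  mu[n == 0] <- NA; se[n == 0] <- NA
  structure(list(lon = ref$lon, lat = ref$lat, mean = mu, se = se,
                 n_days = n), class = "seasonal_composite")
}
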