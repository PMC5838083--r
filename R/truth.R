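# Ground-truth habitat preference used by the synthetic track generator
# and by parameter-recovery tests. The preference is a linear predictor on
# the *transformed* covariate scale (the same scale the habitat model sees:
# log10 chlorophyll, log10 EKE, sqrt bathymetry SD).

# covariates the truth may reference and the transform each receives
TRANSFORMED_VARS <- c("sst", "chl", "sla", "sla_sd", "sst_sd", "wind_v",
                      "bathymetry", "bathymetry_sd", "eke")

# floor applied to EKE before log10 in generator-side lookups only, so the
# preference stays finite where the eddy field has an exact stagnation point
EKE_FLOOR <- 1e-3

#' Define a ground-truth habitat preference
#'
#' @param intercept Intercept on the logit scale.
#' @param terms Named list, one entry per covariate, each a list with
#'   `shape` ("linear" or "quadratic") and coefficients `beta`
#'   (and `beta2` for quadratic: contribution `beta*x + beta2*x^2`).
#'   Covariate names must be among the environmental variables
#'   (`sst`, `chl`, `sla`, `sla_sd`, `sst_sd`, `wind_v`, `bathymetry`,
#'   `bathymetry_sd`, `eke`); coefficients apply on the transformed scale.
#' @return Object of class `truth_preference`.
#' @export
truth_preference <- function(intercept = 0, terms = list()) {
  if (length(terms) > 0) {
    bad <- setdiff(names(terms), TRANSFORMED_VARS)
    if (length(bad) > 0)
      stop("unknown covariate(s) in truth: ", paste(bad, collapse = ", "))
  }
  structure(list(intercept = intercept, terms = terms),
            class = "truth_preference")
}

# transformed covariate values at nearest grid cells (generator-side lookup;
# the matchup module uses box means instead)
env_transformed_at <- function(env, lon, lat, date, vars = TRANSFORMED_VARS) {
  out <- list()
  for (v in vars) {
    raw <- switch(v,
      eke = {
        uu <- env_cell_value(env, "u", lon, lat, date)
        vv <- env_cell_value(env, "v", lon, lat, date)
        compute_eke(uu, vv)
      },
      env_cell_value(env, v, lon, lat, date))
    out[[v]] <- switch(v,
      chl = log10(raw),
      eke = log10(pmax(raw, EKE_FLOOR)),
      bathymetry_sd = sqrt(pmax(raw, 0)),
      raw)
  }
  as.data.frame(out)
}

eval_truth_term <- function(term, x) {
  switch(term$shape,
    linear = term$beta * x,
    quadratic = term$beta * x + term$beta2 * x^2,
    stop("unknown truth term shape: ", term$shape))
}

# truth linear predictor at vectorized positions
truth_eta <- function(env, truth, lon, lat, date) {
  vals <- env_transformed_at(env, lon, lat, date, names(truth$terms))
  eta <- rep(truth$intercept, length(lon))
  for (v in names(truth$terms))
    eta <- eta + eval_truth_term(truth$terms[[v]], vals[[v]])
  eta
}

#' Ground-truth suitability surface
#'
#' Inverse-logit of the truth linear predictor evaluated on the field grid
#' for one date; land cells are masked `NA`.
#'
#' @param env An `env_fields` object.
#' @param truth A [truth_preference()].
#' @param date Date within the field set's coverage.
#' @return Matrix `[lon, lat]` of suitabilities in `[0, 1]`, with
#'   attributes `lon`, `lat`, `date`.
#' @export
truth_surface <- function(env, truth, date) {
  date <- as.Date(date)
  if (date < min(env$time) || date > max(env$time))
    stop("date outside field coverage")
  g <- expand.grid(lon = env$lon, lat = env$lat)
  eta <- truth_eta(env, truth, g$lon, g$lat, date)
  p <- stats::plogis(eta)
  p[is_land(env, g$lon, g$lat)] <- NA
  m <- matrix(p, length(env$lon), length(env$lat))
  attr(m, "lon") <- env$lon; attr(m, "lat") <- env$lat; attr(m, "date") <- date
  m
}
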