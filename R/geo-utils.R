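# Geodesy helpers shared across the pipeline. All distances are haversine
# great-circle distances on a sphere of radius 6371.0 km; bearings are
# initial bearings in degrees clockwise from true north.

EARTH_RADIUS_KM <- 6371.0

#' Great-circle distance between two points
#'
#' Haversine distance on a sphere of radius 6371.0 km, the convention used
#' throughout the package for trip metrics, step lengths and
#' distance-from-colony covariates.
#'
#' @param p1,p2 Numeric vectors `c(lon, lat)` in decimal degrees, or
#'   two-column matrices of such points (recycled row-wise).
#' @return Distance(s) in kilometres.
#' @export
great_circle_km <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM * 1000) / 1000
}

#' Initial bearing between two points
#'
#' @param p1,p2 `c(lon, lat)` points or two-column matrices.
#' @return Bearing(s) in degrees, wrapped into `[0, 360)`. Coincident
#'   points return 0 by convention.
#' @export
initial_bearing_deg <- function(p1, p2) {
  b <- geosphere::bearing(p1, p2) %% 360
  b[is.na(b) | !is.finite(b)] <- 0
  # coincident points have no defined bearing; use 0 by convention
  b[great_circle_km(p1, p2) == 0] <- 0
  b
}

#' Destination point given start, bearing and distance
#'
#' @param p `c(lon, lat)` start point (or matrix).
#' @param bearing_deg Bearing in degrees from north.
#' @param distance_km Great-circle distance in km.
#' @return Matrix with columns lon, lat.
#' @export
destination_point <- function(p, bearing_deg, distance_km) {
  geosphere::destPoint(p, bearing_deg, distance_km * 1000,
                       r = EARTH_RADIUS_KM * 1000)
}

#' Wrap an angle into (-180, 180]
#' @param x Angle(s) in degrees.
#' @return Wrapped angle(s).
#' @export
wrap_angle_deg <- function(x) {
  y <- x %% 360
  ifelse(y > 180, y - 360, y)
}

# Absolute angular difference of two bearings, wrapped into [0, 180].
bearing_diff_deg <- function(a, b) {
  abs(wrap_angle_deg(a - b))
}

#' Deterministic seed splitting
#'
#' All randomness in the package flows from a single integer master seed.
#' Sub-seeds for independent stages or replicates are drawn once from the
#' master seed so that stages are reproducible in isolation.
#'
#' @param seed Master integer seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of `n` sub-seeds in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
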