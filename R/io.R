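# Plain-text readers and writers for the pipeline's interchange formats:
# track CSV, gridded-field long CSV, trip/matchup tables, UD contour
# GeoJSON and surface CSV.

#' Write raw tracks to CSV
#'
#' Columns: `animal_id`, `timestamp` (ISO 8601 UTC), `lon` (-180..180),
#' `lat`, `lc` (optional quality class).
#'
#' @param tracks A `raw_tracks` list or a single track data.frame.
#' @param path Output CSV path.
#' @export
write_tracks_csv <- function(tracks, path) {
  df <- if (inherits(tracks, "raw_tracks")) do.call(rbind, tracks) else tracks
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read raw tracks from CSV
#'
#' @param path CSV with `animal_id`, `timestamp`, `lon`, `lat`
#'   (optionally `lc`).
#' @return A `raw_tracks` list, one data.frame per animal, time-sorted.
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "timestamp", "lon", "lat")
  if (!all(need %in% names(df)))
    stop("track CSV must have columns ", paste(need, collapse = ", "))
  df$timestamp <- as.POSIXct(df$timestamp,
                             format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  if (anyNA(df$timestamp)) stop("unparseable timestamps in ", path)
  if (!"lc" %in% names(df)) df$lc <- NA_character_
  out <- lapply(split(df, df$animal_id), function(x) {
    x <- x[order(x$timestamp), ]
    rownames(x) <- NULL
    x
  })
  structure(out, class = "raw_tracks")
}

#' Write a field set as long-format CSV
#'
#' One file with columns `variable`, `date` (empty for static layers),
#' `lon`, `lat`, `value`. Bathymetry is negative metres below sea level.
#'
#' @param env An `env_fields` object.
#' @param path Output CSV path.
#' @export
write_fields_csv <- function(env, path) {
  g <- expand.grid(lon = env$lon, lat = env$lat)
  parts <- list()
  for (v in names(env$static))
    parts[[length(parts) + 1]] <- data.frame(
      variable = v, date = "", lon = g$lon, lat = g$lat,
      value = as.vector(env$static[[v]]))
  for (v in names(env$vars)) for (k in seq_along(env$time))
    parts[[length(parts) + 1]] <- data.frame(
      variable = v, date = format(env$time[k]), lon = g$lon, lat = g$lat,
      value = as.vector(env$vars[[v]][, , k]))
  utils::write.csv(do.call(rbind, parts), path, row.names = FALSE)
  invisible(path)
}

#' Read a field set from long-format CSV
#'
#' Inverse of [write_fields_csv()]; the grid and time axis are
#' reconstructed from the coordinate columns.
#'
#' @param path CSV path.
#' @return An `env_fields` object (without a scenario).
#' @export
read_fields_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lon <- sort(unique(df$lon)); lat <- sort(unique(df$lat))
  dyn <- df[df$date != "", ]
  time <- sort(unique(as.Date(dyn$date)))
  vars <- list(); static <- list()
  for (v in unique(df$variable)) {
    sub <- df[df$variable == v, ]
    if (all(sub$date == "")) {
      m <- matrix(NA_real_, length(lon), length(lat))
      m[cbind(match(sub$lon, lon), match(sub$lat, lat))] <- sub$value
      static[[v]] <- m
    } else {
      a <- array(NA_real_, c(length(lon), length(lat), length(time)))
      a[cbind(match(sub$lon, lon), match(sub$lat, lat),
              match(as.Date(sub$date), time))] <- sub$value
      vars[[v]] <- a
    }
  }
  structure(list(lon = lon, lat = lat, time = time, vars = vars,
                 static = static,
                 scenario = list(grid_step = diff(lon[1:2]))),
            class = "env_fields")
}

#' Write utilization-distribution contours as GeoJSON
#'
#' One MultiPolygon feature per probability level.
#'
#' @param ud A `utilization_distribution`.
#' @param path Output `.geojson` path.
#' @export
write_ud_geojson <- function(ud, path) {
  features <- lapply(seq_along(ud$levels), function(i) {
    polys <- lapply(ud$contours[[i]], function(p) {
      ring <- cbind(p$lon, p$lat)
      if (!all(ring[1, ] == ring[nrow(ring), ]))
        ring <- rbind(ring, ring[1, ])
      list(lapply(seq_len(nrow(ring)), function(r) as.numeric(ring[r, ])))
    })
    list(type = "Feature",
         properties = list(level = ud$levels[i],
                           area_km2 = as.numeric(ud$areas_km2[i])),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

#' Write a prediction surface (or composite layer) as CSV
#' @param surface A `prediction_surface`, or a `seasonal_composite` with
#'   `layer` choosing `"mean"` or `"se"`.
#' @param path Output CSV path.
#' @param layer Composite layer name (ignored for daily surfaces).
#' @export
write_surface_csv <- function(surface, path, layer = "mean") {
  if (inherits(surface, "seasonal_composite")) {
    vals <- surface[[layer]]
  } else vals <- surface$values
  g <- expand.grid(lon = surface$lon, lat = surface$lat)
  g$value <- as.vector(vals)
  utils::write.csv(g, path, row.names = FALSE)
  invisible(path)
}
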