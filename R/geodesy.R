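#' Central angle between points on the sphere
#'
#' Great-circle angular separation of two geographic points,
#' `acos(sin(lat1) sin(lat2) + cos(lat1) cos(lat2) cos(dlon))`,
#' evaluated in its haversine reformulation
#' `2 asin(sqrt(sin^2(dlat/2) + cos(lat1) cos(lat2) sin^2(dlon/2)))`:
#' the two are the same quantity, but the haversine form does not lose
#' precision for nearby points (coincident points return exactly 0,
#' where the plain arc-cosine would return about `1e-8` from rounding).
#' On the unit sphere the central angle in radians is the distance;
#' multiply by a radius for a length.
#'
#' @param lat1,lon1 Latitude and longitude of the start point, degrees.
#' @param lat2,lon2 Latitude and longitude of the end point, degrees.
#' @return Central angle(s) in radians, in `[0, pi]`. Vectorised over all
#'   four arguments.
#' @examples
#' central_angle(0, 0, 0, 90) # quarter great circle: pi/2
#' @export
central_angle <- function(lat1, lon1, lat2, lon2) {
  check_finite(c(lat1, lon1, lat2, lon2), "coordinates")
  if (any(abs(c(lat1, lat2)) > 90)) {
    abort_circmag("Latitudes must lie in [-90, 90].", "invalid_input")
  }
  p1 <- deg2rad(lat1)
  p2 <- deg2rad(lat2)
  dl <- deg2rad(norm_lon(lon2) - norm_lon(lon1))
  hav <- sin((p2 - p1) / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * asin(pmin(1, sqrt(pmax(0, hav))))
}

#' Initial bearing (forward azimuth) along the great circle
#'
#' Direction of departure from the first point toward the second,
#' measured clockwise from geographic north. The longitude difference is
#' wrapped to `(-pi, pi]` so crossings of the antimeridian take the short
#' way around.
#'
#' @inheritParams central_angle
#' @return Bearing(s) in radians in `[0, 2*pi)`. Vectorised.
#' @details The bearing is undefined when the two points coincide
#'   (central angle below `1e-12` rad) or when the start point is a pole;
#'   both raise an error.
#' @examples
#' initial_bearing(0, 0, 0, 10) # due east: pi/2
#' initial_bearing(0, 0, 10, 0) # due north: 0
#' @export
initial_bearing <- function(lat1, lon1, lat2, lon2) {
  check_finite(c(lat1, lon1, lat2, lon2), "coordinates")
  if (any(abs(c(lat1, lat2)) > 90)) {
    abort_circmag("Latitudes must lie in [-90, 90].", "invalid_input")
  }
  ca <- central_angle(lat1, lon1, lat2, lon2)
  if (any(ca < 1e-12)) {
    abort_circmag(
      "Bearing is undefined for coincident points.",
      "undefined_bearing"
    )
  }
  if (any(abs(lat1) >= 90)) {
    abort_circmag(
      "Bearing is undefined from a geographic pole.",
      "undefined_bearing"
    )
  }
  p1 <- deg2rad(lat1)
  p2 <- deg2rad(lat2)
  dl <- wrap_pi(deg2rad(lon2 - lon1))
  b <- atan2(
    sin(dl) * cos(p2),
    cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl)
  )
  wrap_2pi(b)
}

#' Direction-change series of an ordered track
#'
#' Turns timed geographic positions into the circular response analysed
#' downstream: either the forward azimuth of each consecutive segment
#' (`mode = "bearing"`, the default) or the wrapped difference of
#' consecutive bearings (`mode = "turn_angle"`). Zero-length segments
#' (repeated positions) are dropped with a warning before angles are
#' computed.
#'
#' @param tracks A data frame with columns `species`, `timestamp`
#'   (anything [decimal_year()] accepts), `lat` and `lon` (degrees). May
#'   contain several species; each is processed independently.
#' @param mode `"bearing"` or `"turn_angle"`.
#' @return A tibble with one row per angle: `species`, `timestamp`,
#'   `time` (decimal year), `lat`, `lon` (the anchor point, i.e. the
#'   start of the segment the angle belongs to) and `theta` in
#'   `[0, 2*pi)` radians. For a track of `k` distinct points the series
#'   has `k - 1` (`bearing`) or `k - 2` (`turn_angle`) rows.
#' @examples
#' trk <- tibble::tibble(
#'   species = "demo", timestamp = 2020 + (0:3) / 365,
#'   lat = c(0, 0, 0, 0), lon = c(0, 1, 2, 3)
#' )
#' direction_series(trk)
#' @export
direction_series <- function(tracks, mode = c("bearing", "turn_angle")) {
  mode <- rlang::arg_match(mode)
  need <- c("species", "timestamp", "lat", "lon")
  missing_cols <- setdiff(need, names(tracks))
  if (length(missing_cols) > 0) {
    abort_circmag(
      paste0(
        "`tracks` is missing column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      "schema"
    )
  }
  min_pts <- if (mode == "bearing") 2L else 3L
  out <- dplyr::group_by(as_tibble(tracks), .data$species)
  out <- dplyr::group_map(out, function(df, key) {
    df$time <- decimal_year(df$timestamp)
    df <- df[order(df$time), , drop = FALSE]
    if (anyDuplicated(df$time)) {
      abort_circmag(
        paste0(
          "Timestamps must be strictly increasing within species '",
          key$species, "'."
        ),
        "invalid_input"
      )
    }
    # drop zero-length segments: keep a point only if it moved
    dropped <- nrow(df)
    df <- drop_repeated_points(df)
    dropped <- dropped - nrow(df)
    if (dropped > 0) {
      warn(paste0(
        "Dropped ", dropped, " repeated position(s) in species '",
        key$species, "'."
      ))
    }
    if (nrow(df) < min_pts) {
      abort_circmag(
        paste0(
          "Species '", key$species, "' has fewer than ", min_pts,
          " distinct points for mode = '", mode, "'."
        ),
        "too_short_track"
      )
    }
    n <- nrow(df)
    brg <- initial_bearing(
      df$lat[-n], df$lon[-n], df$lat[-1], df$lon[-1]
    )
    if (mode == "bearing") {
      theta <- brg
      anchor <- seq_len(n - 1)
    } else {
      # turn at interior vertex j, anchored to the start of the
      # outgoing segment (the vertex itself)
      theta <- wrap_2pi(diff(brg))
      anchor <- seq(2L, n - 1L)
    }
    tibble(
      species = key$species,
      timestamp = df$timestamp[anchor],
      time = df$time[anchor],
      lat = df$lat[anchor],
      lon = df$lon[anchor],
      theta = theta
    )
  })
  out <- dplyr::bind_rows(out)
  attr(out, "mode") <- mode
  out
}

# remove points that did not move relative to the last kept point
# (zero-length segments make the bearing undefined)
drop_repeated_points <- function(df) {
  keep <- rep(TRUE, nrow(df))
  i <- 1L
  for (j in seq_len(nrow(df))[-1]) {
    ca <- central_angle(df$lat[i], df$lon[i], df$lat[j], df$lon[j])
    if (ca < 1e-12) keep[j] <- FALSE else i <- j
  }
  df[keep, , drop = FALSE]
}
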