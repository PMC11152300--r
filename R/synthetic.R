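#' Synthetic Gauss coefficient sets
#'
#' Fixture-grade field models with known structure. `"dipole"` has the
#' single axial term `g_1^0 = -scale_nT` (the minus sign giving a
#' northern-hemisphere-down field like the Earth's), for which
#' inclination obeys `tan(I) = 2 tan(latitude)` and declination is
#' identically zero. `"randomized"` draws every `g_n^m`, `h_n^m` from a
#' normal distribution whose scale decays as `scale_nT * 0.3^n`, with
#' `h_n^0 = 0` by convention, giving a smooth but spatially varying
#' field in both declination and inclination. The axial dipole term of
#' a randomized set is pinned at `g_1^0 = -scale_nT`, mirroring the
#' real field, where the axial dipole dominates every other
#' coefficient; only the remaining terms are randomised. This keeps
#' inclination increasing toward the north over most of the globe (as
#' on Earth), which in turn makes inclination-coupled synthetic walks
#' self-stabilising rather than pole-seeking.
#'
#' @param kind `"dipole"` or `"randomized"`.
#' @param n_max Truncation degree.
#' @param scale_nT Field scale in nT; the default is of the order of the
#'   Earth's dipole term.
#' @param epoch Reference epoch, decimal year.
#' @param seed Optional integer seed (randomized kind).
#' @param path Optional file path; when given the set is also written
#'   with [write_cof()].
#' @return A [gauss_coefficients()] object.
#' @export
synthetic_coefficients <- function(kind = c("dipole", "randomized"),
                                   n_max = 12, scale_nT = 30000,
                                   epoch = 2020, seed = NULL,
                                   path = NULL) {
  kind <- rlang::arg_match(kind)
  if (n_max < 1) abort_circmag("`n_max` must be >= 1.", "invalid_input")
  if (kind == "dipole") {
    out <- gauss_coefficients(
      n = 1, m = 0, g = -scale_nT, h = 0,
      epoch = epoch, model_name = "SYNTH-DIPOLE", n_max = n_max
    )
  } else {
    grid <- do.call(rbind, lapply(seq_len(n_max), function(n) {
      cbind(n = n, m = 0:n)
    }))
    k <- nrow(grid)
    draws <- with_seed_if(seed, {
      sdv <- scale_nT * 0.3^grid[, "n"]
      g <- stats::rnorm(k, 0, sdv)
      h <- stats::rnorm(k, 0, sdv)
      cbind(g, h)
    })
    draws[grid[, "m"] == 0, 2] <- 0
    # Earth-like anchor: dominant axial dipole of fixed polarity
    dip_row <- grid[, "n"] == 1 & grid[, "m"] == 0
    draws[dip_row, 1] <- -scale_nT
    out <- gauss_coefficients(
      n = grid[, "n"], m = grid[, "m"],
      g = draws[, 1], h = draws[, 2],
      epoch = epoch, model_name = "SYNTH-RANDOM", n_max = n_max
    )
  }
  if (!is.null(path)) write_cof(out, path)
  out
}

# one spherical dead-reckoning step: destination after moving along the
# great circle at azimuth `bearing` through central angle `step`
gc_destination <- function(lat, lon, bearing, step) {
  phi <- deg2rad(lat)
  lam <- deg2rad(lon)
  phi2 <- asin(sin(phi) * cos(step) + cos(phi) * sin(step) * cos(bearing))
  lam2 <- lam + atan2(
    sin(bearing) * sin(step) * cos(phi),
    cos(step) - sin(phi) * sin(phi2)
  )
  c(lat = rad2deg(phi2), lon = norm_lon(rad2deg(lam2)))
}

#' Simulate a directional-random-walk track on the sphere
#'
#' Generates a timed track whose per-segment headings are independent
#' von Mises draws: at each step a heading is drawn from
#' `VM(mu, kappa)` and the position advances along the great circle at
#' that azimuth through central angle `step_angle` (spherical dead
#' reckoning), so that [direction_series()] recovers exactly the drawn
#' headings. Defaults emulate a mid-latitude migrant logged once per
#' day: segments of about 64 km (`step_angle = 0.01` rad), eastward
#' mean heading, moderate directional concentration.
#'
#' @param n_points Number of track points (`n_points - 1` segments).
#' @param start_lat,start_lon Starting position, degrees.
#' @param step_angle Central angle per segment, radians, in
#'   `(0, pi/2)`.
#' @param mu,kappa von Mises heading parameters (radians /
#'   concentration).
#' @param species Label for the `species` column.
#' @param start_time First timestamp as a decimal year.
#' @param time_step Time between fixes in years (default one day).
#' @param seed Optional integer seed.
#' @return A tibble with columns `species`, `timestamp` (POSIXct, UTC),
#'   `time` (decimal year), `lat`, `lon`.
#' @examples
#' trk <- simulate_track_vm(50, seed = 1)
#' head(direction_series(trk))
#' @export
simulate_track_vm <- function(n_points = 500, start_lat = 45,
                              start_lon = -100, step_angle = 0.01,
                              mu = pi / 2, kappa = 4,
                              species = "synthetic",
                              start_time = 2020.0, time_step = 1 / 365,
                              seed = NULL) {
  sim <- simulate_coupled_track(
    n_points = n_points, start_lat = start_lat, start_lon = start_lon,
    step_angle = step_angle, mu = mu, kappa = kappa, coupling = 0,
    coeffs = NULL, species = species, start_time = start_time,
    time_step = time_step, seed = seed
  )
  sim$track
}

#' Simulate a track with planted magnetic coupling
#'
#' Generative counterpart of the package's regression model: at each
#' step the declination or inclination angle `M` is evaluated at the
#' bird's current position and time (`covariate_mode = "point"`) or as
#' the wrapped change since the previous position (`"delta"`), and the
#' heading is drawn from a von Mises distribution whose mean direction
#' is shifted to `mu + coupling * M` with concentration `kappa`.
#' `coupling = 0` reproduces [simulate_track_vm()] draw for draw under
#' the same seed. The per-step covariate values, mean directions and
#' drawn headings are returned as ground truth so every downstream
#' estimate can be checked against the planted signal.
#'
#' The default `covariate_mode = "point"` makes the covariate
#' exogenous: it is fixed before the heading is drawn. In `"delta"`
#' mode the analysed covariate (the field change across a segment) is
#' partly *caused by* the drawn heading, which is scientifically
#' interesting but makes an independence null unattainable by
#' construction; see the methods vignette.
#'
#' @inheritParams simulate_track_vm
#' @param coeffs A [gauss_coefficients()] object (required when
#'   `coupling > 0` or ground-truth covariates are wanted; `NULL` gives
#'   a zero covariate).
#' @param covariate `"inclination"` or `"declination"`.
#' @param coupling Dependence strength in `[0, 1]`.
#' @param covariate_mode `"point"` (field angle at the current
#'   position) or `"delta"` (wrapped change since the previous
#'   position; zero at the first step).
#' @return An object of class `circmag_sim`: a list with `track` (as in
#'   [simulate_track_vm()]), `truth` (a tibble with per-segment
#'   `covariate` in radians, `heading_mean` and `heading`) and `params`
#'   (the resolved configuration, including the planted coupling).
#' @export
simulate_coupled_track <- function(n_points = 500, start_lat = 45,
                                   start_lon = -100, step_angle = 0.01,
                                   mu = pi / 2, kappa = 4,
                                   coeffs = NULL,
                                   covariate = c(
                                     "inclination",
                                     "declination"
                                   ),
                                   coupling = 0.5,
                                   covariate_mode = c("point", "delta"),
                                   species = "synthetic",
                                   start_time = 2020.0,
                                   time_step = 1 / 365,
                                   seed = NULL) {
  covariate <- rlang::arg_match(covariate)
  covariate_mode <- rlang::arg_match(covariate_mode)
  if (n_points < 3) abort_circmag("`n_points` must be >= 3.", "invalid_input")
  if (kappa < 0) abort_circmag("`kappa` must be >= 0.", "invalid_input")
  if (coupling < 0 || coupling > 1) {
    abort_circmag("`coupling` must lie in [0, 1].", "invalid_input")
  }
  if (step_angle <= 0 || step_angle >= pi / 2) {
    abort_circmag("`step_angle` must lie in (0, pi/2).", "invalid_input")
  }
  if (coupling > 0 && is.null(coeffs)) {
    abort_circmag(
      "A coefficient set is required when `coupling` > 0.",
      "invalid_input"
    )
  }

  n_seg <- n_points - 1
  lat <- numeric(n_points)
  lon <- numeric(n_points)
  lat[1] <- start_lat
  lon[1] <- start_lon
  times <- start_time + (seq_len(n_points) - 1) * time_step
  mats <- if (!is.null(coeffs)) coef_matrices(coeffs)
  cov_angle <- function(la, lo, tt) {
    if (is.null(coeffs)) return(0)
    v <- field_core(coeffs, la, lo, coeffs$a, tt, coeffs$n_max, mats)
    if (covariate == "declination") {
      atan2(v[2], v[1])
    } else {
      atan2(v[3], sqrt(v[1]^2 + v[2]^2))
    }
  }
  covariate_vals <- numeric(n_seg)
  heading_mean <- numeric(n_seg)
  heading <- numeric(n_seg)
  prev_angle <- NA_real_
  with_seed_if(seed, {
    for (i in seq_len(n_seg)) {
      here <- cov_angle(lat[i], lon[i], times[i])
      m_i <- if (covariate_mode == "point") {
        here
      } else if (is.na(prev_angle)) {
        0
      } else {
        wrap_pi(here - prev_angle)
      }
      prev_angle <- here
      covariate_vals[i] <- m_i
      heading_mean[i] <- wrap_2pi(mu + coupling * m_i)
      heading[i] <- wrap_2pi(heading_mean[i] + rvm_centred(1, kappa))
      # guard before stepping: a single step must not be able to reach
      # the polar cap, where bearings degenerate
      if (abs(lat[i]) + rad2deg(step_angle) > 89.9) {
        abort_circmag(
          "Track escaped toward a pole; use fewer points or a smaller step.",
          "polar_escape"
        )
      }
      dest <- gc_destination(lat[i], lon[i], heading[i], step_angle)
      lat[i + 1] <- dest["lat"]
      lon[i + 1] <- dest["lon"]
    }
  })
  track <- tibble(
    species = species,
    timestamp = lubridate::date_decimal(times, tz = "UTC"),
    time = times,
    lat = lat, lon = lon
  )
  structure(
    list(
      track = track,
      truth = tibble(
        step = seq_len(n_seg),
        covariate = covariate_vals,
        heading_mean = heading_mean,
        heading = heading
      ),
      params = list(
        n_points = n_points, start_lat = start_lat,
        start_lon = start_lon, step_angle = step_angle, mu = mu,
        kappa = kappa, coupling = coupling, covariate = covariate,
        covariate_mode = covariate_mode, species = species,
        start_time = start_time, time_step = time_step, seed = seed
      )
    ),
    class = "circmag_sim"
  )
}

#' @export
print.circmag_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<circmag_sim> %d points, coupling %.2f to %s (%s mode), mu = %.2f, kappa = %.2f\n",
    p$n_points, p$coupling, p$covariate, p$covariate_mode, p$mu, p$kappa
  ))
  invisible(x)
}

#' Write a track or simulation ground truth to disk
#'
#' `write_track_csv()` writes the pipeline's input dialect (columns
#' `species`, `timestamp`, `location-lat`, `location-long`).
#' `write_sim_truth()` stores the planted parameters and per-step
#' covariates of a [simulate_coupled_track()] result as a JSON sidecar.
#'
#' @param track A track tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(track, path) {
  out <- tibble(
    species = track$species,
    timestamp = format(track$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    `location-lat` = track$lat,
    `location-long` = track$lon
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_track_csv
#' @param sim A `circmag_sim` object.
#' @export
write_sim_truth <- function(sim, path) {
  stopifnot(inherits(sim, "circmag_sim"))
  jsonlite::write_json(
    list(params = sim$params, truth = sim$truth),
    path,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
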