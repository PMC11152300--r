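#' Schmidt semi-normalised associated Legendre functions
#'
#' Values and latitude derivatives of the Schmidt semi-normalised
#' associated Legendre functions used in geomagnetic field synthesis:
#' for `m = 0` the unnormalised Legendre polynomial `P_n`, and for
#' `m > 0` the function scaled by `sqrt(2 (n-m)! / (n+m)!)`, without the
#' Condon-Shortley phase. Computed by stable three-term recursion in the
#' argument `sin(phi)` together with the analytically differentiated
#' recursion for `d/dphi`.
#'
#' @param n_max Maximum degree (>= 1).
#' @param phi_prime Geocentric latitude in radians, `|phi_prime| <= pi/2`.
#' @return A list with matrices `p` and `dp` of dimension
#'   `(n_max + 1) x (n_max + 1)`; entry `[n + 1, m + 1]` holds degree
#'   `n`, order `m`. `dp` is the derivative with respect to latitude.
#' @examples
#' schmidt_legendre(2, pi / 6)$p[2, 1] # P_1(sin 30 deg) = 0.5
#' @export
schmidt_legendre <- function(n_max, phi_prime) {
  if (n_max < 1) abort_circmag("`n_max` must be >= 1.", "invalid_input")
  if (abs(phi_prime) > pi / 2 + 1e-12) {
    abort_circmag("`phi_prime` must lie in [-pi/2, pi/2].", "invalid_input")
  }
  x <- sin(phi_prime)
  s <- cos(phi_prime) # >= 0 on the domain
  p <- matrix(0, n_max + 1, n_max + 1)
  dp <- matrix(0, n_max + 1, n_max + 1)
  p[1, 1] <- 1
  for (n in seq_len(n_max)) {
    # diagonal term: Schmidt factor sqrt((2n-1)/(2n)) for n >= 2
    f <- if (n == 1) 1 else sqrt((2 * n - 1) / (2 * n))
    p[n + 1, n + 1] <- f * s * p[n, n]
    dp[n + 1, n + 1] <- f * (-x * p[n, n] + s * dp[n, n])
    for (m in 0:(n - 1)) {
      k1 <- sqrt((n + m) * (n - m))
      k2 <- sqrt((n - 1 + m) * (n - 1 - m)) # 0 when m = n - 1
      p2 <- if (n >= 2) p[n - 1, m + 1] else 0
      dp2 <- if (n >= 2) dp[n - 1, m + 1] else 0
      p[n + 1, m + 1] <- ((2 * n - 1) * x * p[n, m + 1] - k2 * p2) / k1
      dp[n + 1, m + 1] <-
        ((2 * n - 1) * (s * p[n, m + 1] + x * dp[n, m + 1]) - k2 * dp2) / k1
    }
  }
  list(p = p, dp = dp)
}

# Resolve the (g, h) matrices of a set at time t (linear + optional
# quadratic secular variation), truncated at n_max. `mats` lets callers
# hoist the matrix construction out of per-point loops.
gh_at_time <- function(coeffs, t, n_max, mats = coef_matrices(coeffs)) {
  dt <- t - coeffs$epoch
  g <- mats$g + mats$g_dot * dt + mats$g_ddot * dt^2
  h <- mats$h + mats$h_dot * dt + mats$h_ddot * dt^2
  list(g = g[seq_len(n_max), , drop = FALSE],
       h = h[seq_len(n_max), , drop = FALSE])
}

resolve_nmax <- function(coeffs, n_max) {
  n_max <- n_max %||% coeffs$n_max
  if (n_max > coeffs$n_max) {
    abort_circmag(
      "`n_max` exceeds the truncation degree of the coefficient set.",
      "invalid_input"
    )
  }
  as.integer(n_max)
}

#' Geomagnetic scalar potential
#'
#' Spherical-harmonic synthesis of the main-field scalar potential
#' `V = a * sum_n sum_m (a/r)^(n+1) (g cos(m lambda) + h sin(m lambda))
#' P_nm(sin phi)` in nT.m, with coefficients first propagated to time
#' `t`.
#'
#' @param coeffs A [gauss_coefficients()] object.
#' @param lat,lon Geocentric latitude and longitude in degrees.
#' @param r Geocentric radius in metres (defaults to the reference
#'   radius `a`).
#' @param t Decimal year (defaults to the set's epoch).
#' @param n_max Optional truncation degree, at most the set's own.
#' @return Numeric vector of potentials, nT.m. Vectorised over points.
#' @export
scalar_potential <- function(coeffs, lat, lon, r = coeffs$a,
                             t = coeffs$epoch, n_max = NULL) {
  stopifnot(inherits(coeffs, "gauss_coef"))
  n_max <- resolve_nmax(coeffs, n_max)
  k <- max(length(lat), length(lon), length(r), length(t))
  lat <- rep_len(lat, k); lon <- rep_len(lon, k)
  r <- rep_len(r, k); t <- rep_len(t, k)
  if (any(r <= 0)) abort_circmag("`r` must be positive.", "domain")
  a <- coeffs$a
  mats <- coef_matrices(coeffs)
  vapply(seq_len(k), function(i) {
    gh <- gh_at_time(coeffs, t[i], n_max, mats)
    leg <- schmidt_legendre(n_max, deg2rad(lat[i]))
    lam <- deg2rad(lon[i])
    v <- 0
    for (n in seq_len(n_max)) {
      m <- 0:n
      term <- sum(
        (gh$g[n, m + 1] * cos(m * lam) + gh$h[n, m + 1] * sin(m * lam)) *
          leg$p[n + 1, m + 1]
      )
      v <- v + (a / r[i])^(n + 1) * term
    }
    a * v
  }, numeric(1))
}

#' Geomagnetic field vector
#'
#' Evaluates the main field in local geodetic-style components:
#' `x_north` (northward), `y_east` (eastward) and `z_down` (vertically
#' down), in nT, as the negative spatial gradient of the scalar
#' potential on the sphere. Latitudes are treated as geocentric on the
#' sphere `r = a`; the exact poles are excluded because the eastward
#' component carries a `1/cos(phi)` factor.
#'
#' @inheritParams scalar_potential
#' @return A tibble with columns `x_north`, `y_east`, `z_down` (nT),
#'   one row per point.
#' @examples
#' dip <- gauss_coefficients(n = 1, m = 0, g = -30000, h = 0, epoch = 2020)
#' field_vector(dip, lat = 0, lon = 0) # purely northward at the equator
#' @export
field_vector <- function(coeffs, lat, lon, r = coeffs$a,
                         t = coeffs$epoch, n_max = NULL) {
  stopifnot(inherits(coeffs, "gauss_coef"))
  n_max <- resolve_nmax(coeffs, n_max)
  k <- max(length(lat), length(lon), length(r), length(t))
  lat <- rep_len(lat, k); lon <- rep_len(lon, k)
  r <- rep_len(r, k); t <- rep_len(t, k)
  if (any(r <= 0)) abort_circmag("`r` must be positive.", "domain")
  if (any(abs(lat) >= 90 - 1e-9)) {
    abort_circmag(
      "Field components are singular at the geographic poles.",
      "pole_singularity"
    )
  }
  mats <- coef_matrices(coeffs)
  out <- matrix(0, k, 3)
  for (i in seq_len(k)) {
    out[i, ] <- field_core(coeffs, lat[i], lon[i], r[i], t[i], n_max, mats)
  }
  tibble(x_north = out[, 1], y_east = out[, 2], z_down = out[, 3])
}

# scalar-point synthesis of (north, east, down) in nT; the hot inner
# loop shared by field_vector() and the track simulator
field_core <- function(coeffs, lat, lon, r, t, n_max, mats) {
  gh <- gh_at_time(coeffs, t, n_max, mats)
  phi <- deg2rad(lat)
  leg <- schmidt_legendre(n_max, phi)
  lam <- deg2rad(lon)
  a <- coeffs$a
  x <- 0; y <- 0; z <- 0
  for (n in seq_len(n_max)) {
    m <- 0:n
    cm <- cos(m * lam); sm <- sin(m * lam)
    gc <- gh$g[n, m + 1]; hc <- gh$h[n, m + 1]
    arn <- (a / r)^(n + 2)
    x <- x - arn * sum((gc * cm + hc * sm) * leg$dp[n + 1, m + 1])
    y <- y + arn * sum(m * (gc * sm - hc * cm) * leg$p[n + 1, m + 1])
    z <- z - arn * (n + 1) * sum((gc * cm + hc * sm) * leg$p[n + 1, m + 1])
  }
  c(x, y / cos(phi), z)
}

#' Declination and inclination of a field vector
#'
#' Declination `D = atan2(Y, X)` is the angle of the horizontal field
#' east of geographic north; inclination `I = atan2(Z, H)` is the dip
#' below the horizontal, with `H = sqrt(X^2 + Y^2)`. Both are reported
#' in degrees, `D` in `(-180, 180]` and `I` in `[-90, 90]`.
#'
#' @param x_north,y_east,z_down Field components in nT, as returned by
#'   [field_vector()]; alternatively pass that tibble as `x_north`.
#' @return A tibble with columns `declination` and `inclination`
#'   (degrees).
#' @export
field_angles <- function(x_north, y_east = NULL, z_down = NULL) {
  if (is.data.frame(x_north)) {
    df <- x_north
    x_north <- df$x_north; y_east <- df$y_east; z_down <- df$z_down
  }
  h <- sqrt(x_north^2 + y_east^2)
  if (any(h < 1e-9)) {
    abort_circmag(
      "Declination is undefined where the horizontal field vanishes.",
      "undefined_declination"
    )
  }
  tibble(
    declination = rad2deg(atan2(y_east, x_north)),
    inclination = rad2deg(atan2(z_down, h))
  )
}

#' Evaluate the field along a table of points
#'
#' Convenience wrapper joining [field_vector()] and [field_angles()]:
#' takes any data frame with `lat`, `lon` and (optionally) `time`
#' columns and returns it with the field components, horizontal and
#' total intensity, declination and inclination appended.
#'
#' @param data A data frame with columns `lat`, `lon` (degrees) and
#'   optionally `time` (decimal year) or `timestamp`.
#' @param coeffs A [gauss_coefficients()] object.
#' @inheritParams scalar_potential
#' @return `data` as a tibble with columns `x_north`, `y_east`,
#'   `z_down`, `h_intensity`, `f_intensity` (nT), `declination` and
#'   `inclination` (degrees) appended.
#' @export
field_at <- function(data, coeffs, r = coeffs$a, n_max = NULL) {
  data <- as_tibble(data)
  t <- if ("time" %in% names(data)) {
    data$time
  } else if ("timestamp" %in% names(data)) {
    decimal_year(data$timestamp)
  } else {
    coeffs$epoch
  }
  fv <- field_vector(coeffs, data$lat, data$lon, r = r, t = t,
    n_max = n_max
  )
  ang <- field_angles(fv)
  dplyr::bind_cols(
    data, fv,
    tibble(
      h_intensity = sqrt(fv$x_north^2 + fv$y_east^2),
      f_intensity = sqrt(fv$x_north^2 + fv$y_east^2 + fv$z_down^2)
    ),
    ang
  )
}
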