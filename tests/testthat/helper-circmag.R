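# Shared fixture builders. Everything is generated in code; no data
# files are shipped.

# axial dipole with g_1^0 = +g (field southward at the equator) unless
# earthlike = TRUE (g_1^0 < 0, Earth-like polarity)
dipole_set <- function(g = 30000, earthlike = FALSE, epoch = 2020) {
  gauss_coefficients(
    n = 1, m = 0, g = if (earthlike) -abs(g) else g, h = 0,
    epoch = epoch
  )
}

random_set <- function(n_max = 8, seed = 42, scale = 30000) {
  synthetic_coefficients(
    "randomized",
    n_max = n_max, scale_nT = scale, seed = seed
  )
}

# a small deterministic multi-point track on the equator heading east
equatorial_track <- function(n = 4, species = "eq") {
  tibble::tibble(
    species = species,
    timestamp = 2020 + (seq_len(n) - 1) / 365,
    lat = rep(0, n),
    lon = seq(0, by = 1, length.out = n)
  )
}

random_points <- function(n, seed, lat_range = c(-80, 80)) {
  withr::with_seed(seed, tibble::tibble(
    lat = runif(n, lat_range[1], lat_range[2]),
    lon = runif(n, -180, 180)
  ))
}

# Schmidt semi-normalised Legendre values via the explicit factorial
# formula: an independent oracle for the recursion.
# P_n(x) by Rodrigues-style polynomial coefficients, differentiated m
# times, times (1 - x^2)^(m/2) and the Schmidt factor.
legendre_oracle <- function(n, m, x) {
  # coefficients of P_n as a polynomial in x (exact in double for n <= 10)
  coefs <- rep(0, n + 1)
  for (k in 0:floor(n / 2)) {
    coefs[n - 2 * k + 1] <- (-1)^k * choose(n, k) * choose(2 * n - 2 * k, n) /
      2^n
  }
  # differentiate m times
  dc <- coefs
  if (m > 0) {
    for (j in seq_len(m)) {
      dc <- dc[-1] * seq_along(dc[-1])
    }
  }
  pnm <- (1 - x^2)^(m / 2) * sum(dc * x^(seq_along(dc) - 1))
  if (m == 0) pnm else sqrt(2 * factorial(n - m) / factorial(n + m)) * pnm
}

expect_angle_equal <- function(a, b, tol = 1e-10) {
  expect_lt(max(abs(wrap_pi(a - b))), tol)
}

# Independent bearing oracle built from vector algebra: interpolate a
# tiny step along the great circle between the two points (spherical
# linear interpolation of the unit vectors) and measure the azimuth of
# the local displacement in the east/north tangent basis.
bearing_oracle <- function(lat1, lon1, lat2, lon2, eps = 1e-7) {
  to_xyz <- function(lat, lon) {
    la <- lat * pi / 180
    lo <- lon * pi / 180
    c(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
  }
  u1 <- to_xyz(lat1, lon1)
  u2 <- to_xyz(lat2, lon2)
  omega <- acos(max(-1, min(1, sum(u1 * u2))))
  p <- (sin((1 - eps) * omega) * u1 + sin(eps * omega) * u2) / sin(omega)
  d <- p - u1
  la <- lat1 * pi / 180
  lo <- lon1 * pi / 180
  east <- c(-sin(lo), cos(lo), 0)
  north <- c(-sin(la) * cos(lo), -sin(la) * sin(lo), cos(la))
  (atan2(sum(d * east), sum(d * north))) %% (2 * pi)
}
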