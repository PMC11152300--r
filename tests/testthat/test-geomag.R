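test_that("coefficient constructor enforces the index invariants", {
  expect_error(
    gauss_coefficients(n = 1, m = 2, g = 1, h = 0, epoch = 2020),
    class = "circmag_format"
  )
  expect_error(
    gauss_coefficients(
      n = c(1, 1), m = c(0, 0), g = 1, h = 0, epoch = 2020
    ),
    class = "circmag_format"
  )
  expect_error(
    gauss_coefficients(n = 1, m = 0, g = 1, h = 5, epoch = 2020),
    class = "circmag_format"
  )
})

test_that("COF files round-trip bit-exactly", {
  set <- random_set(n_max = 3, seed = 5)
  path <- withr::local_tempfile(fileext = ".cof")
  write_cof(set, path)
  back <- read_cof(path)
  expect_identical(back$coef$g, set$coef$g)
  expect_identical(back$coef$h, set$coef$h)
  expect_identical(back$coef$g_dot, set$coef$g_dot)
  expect_identical(back$epoch, set$epoch)
  expect_identical(back$model_name, set$model_name)
})

test_that("COF parser reports malformed content with line numbers", {
  path <- withr::local_tempfile(fileext = ".cof")
  writeLines(c("2020.0 TEST", "1 0 100 0 0 0", "1 2 5 5 0 0"), path)
  expect_error(read_cof(path), "line 3", class = "circmag_format")
  writeLines(c("2020.0 TEST", "1 0 100 0 0 0", "1 0 1 0 0 0"), path)
  expect_error(read_cof(path), class = "circmag_format")
  writeLines(c("2020.0 TEST", "1 0 oops 0 0 0"), path)
  expect_error(read_cof(path), "line 2", class = "circmag_format")
  writeLines("not-a-number TEST", path)
  expect_error(read_cof(path), class = "circmag_format")
})

test_that("dipole fixture parses with n_max = 1", {
  path <- withr::local_tempfile(fileext = ".cof")
  writeLines(
    c("  2020.0   DIPOLE", "  1  0  -30000  0  0  0",
      "  1  1  -1500  4000  0  0", paste(rep("9", 48), collapse = "")
    ),
    path
  )
  set <- read_cof(path)
  expect_equal(set$n_max, 1L)
  expect_equal(nrow(set$coef), 2)
})

test_that("Schmidt Legendre functions match closed forms", {
  leg <- schmidt_legendre(2, pi / 6)
  expect_equal(leg$p[2, 1], 0.5, tolerance = 1e-14) # P_1(sin 30)
  pole <- schmidt_legendre(2, pi / 2)
  expect_equal(pole$p[3, 1], 1, tolerance = 1e-14) # P_2(1)
})

test_that("Legendre recursion matches the factorial-formula oracle", {
  phi <- 0.7
  x <- sin(phi)
  leg <- schmidt_legendre(8, phi)
  for (n in 1:8) {
    for (m in 0:n) {
      expect_equal(
        leg$p[n + 1, m + 1], legendre_oracle(n, m, x),
        tolerance = 1e-11,
        label = sprintf("P(%d,%d)", n, m)
      )
    }
  }
})

test_that("Legendre latitude derivatives match finite differences", {
  phi <- 0.31
  h <- 1e-6
  up <- schmidt_legendre(6, phi + h)$p
  dn <- schmidt_legendre(6, phi - h)$p
  expect_equal(
    schmidt_legendre(6, phi)$dp, (up - dn) / (2 * h),
    tolerance = 1e-6
  )
})

test_that("secular variation propagates linearly and quadratically", {
  base <- gauss_coefficients(
    n = 1, m = 0, g = 100, h = 0, g_dot = 10, epoch = 2000
  )
  expect_equal(coefficients_at_time(base, 2000)$coef$g, 100)
  expect_equal(coefficients_at_time(base, 2002)$coef$g, 120)
  quad <- gauss_coefficients(
    n = 1, m = 0, g = 100, h = 0, g_dot = 10, g_ddot = 1, epoch = 2000
  )
  expect_equal(coefficients_at_time(quad, 2002)$coef$g, 124)
})

test_that("scalar potential matches closed forms and brute force", {
  zero <- gauss_coefficients(n = 1, m = 0, g = 0, h = 0, epoch = 2020)
  expect_equal(scalar_potential(zero, 12, 34), 0)
  g <- 30000
  dip <- dipole_set(g)
  a <- dip$a
  for (lat in c(-60, 0, 45)) {
    for (rfac in c(1, 1.7)) {
      expect_equal(
        scalar_potential(dip, lat, 10, r = rfac * a),
        a * (1 / rfac)^2 * g * sin(lat * pi / 180),
        tolerance = 1e-12
      )
    }
  }
  # brute-force double loop over the expansion for a random set
  set <- random_set(n_max = 5, seed = 9)
  pt <- list(lat = 37.2, lon = -12.5, r = 1.2 * set$a)
  brute <- 0
  leg <- schmidt_legendre(5, pt$lat * pi / 180)
  lam <- pt$lon * pi / 180
  for (i in seq_len(nrow(set$coef))) {
    n <- set$coef$n[i]
    m <- set$coef$m[i]
    brute <- brute + (set$a / pt$r)^(n + 1) *
      (set$coef$g[i] * cos(m * lam) + set$coef$h[i] * sin(m * lam)) *
      leg$p[n + 1, m + 1]
  }
  expect_equal(
    scalar_potential(set, pt$lat, pt$lon, r = pt$r), set$a * brute,
    tolerance = 1e-12
  )
  expect_error(scalar_potential(dip, 0, 0, r = -1), class = "circmag_domain")
})

test_that("dipole field components follow the closed form", {
  g <- 30000
  dip <- dipole_set(g)
  eq <- field_vector(dip, 0, 0)
  expect_equal(unlist(eq), c(x_north = -g, y_east = 0, z_down = 0))
  at60 <- field_vector(dip, 60, 100)
  expect_equal(at60$x_north, -g * cos(pi / 3), tolerance = 1e-12)
  expect_equal(at60$y_east, 0, tolerance = 1e-12)
  expect_equal(at60$z_down, -2 * g * sin(pi / 3), tolerance = 1e-12)
})

test_that("field vector is the negative potential gradient", {
  set <- random_set(n_max = 8, seed = 17)
  pts <- random_points(20, seed = 18)
  a <- set$a
  h_ang <- 1e-6
  for (i in seq_len(nrow(pts))) {
    lat <- pts$lat[i]
    lon <- pts$lon[i]
    r <- a * (0.9 + 0.4 * i / nrow(pts))
    fv <- unlist(field_vector(set, lat, lon, r = r))
    hd <- h_ang * 180 / pi
    x_fd <- -(scalar_potential(set, lat + hd, lon, r = r) -
      scalar_potential(set, lat - hd, lon, r = r)) / (2 * h_ang * r)
    y_fd <- -(scalar_potential(set, lat, lon + hd, r = r) -
      scalar_potential(set, lat, lon - hd, r = r)) /
      (2 * h_ang * r * cos(lat * pi / 180))
    hr <- r * 1e-6
    z_fd <- (scalar_potential(set, lat, lon, r = r + hr) -
      scalar_potential(set, lat, lon, r = r - hr)) / (2 * hr)
    expect_equal(fv[["x_north"]], x_fd, tolerance = 1e-5)
    expect_equal(fv[["y_east"]], y_fd, tolerance = 1e-5)
    expect_equal(fv[["z_down"]], z_fd, tolerance = 1e-5)
  }
})

test_that("field is linear in the coefficients and scales as (a/r)^(n+2)", {
  a_set <- random_set(n_max = 4, seed = 21)
  b_set <- random_set(n_max = 4, seed = 22)
  sum_set <- gauss_coefficients(
    n = a_set$coef$n, m = a_set$coef$m,
    g = a_set$coef$g + b_set$coef$g,
    h = a_set$coef$h + b_set$coef$h,
    epoch = 2020
  )
  pt <- c(33, -117)
  expect_equal(
    unlist(field_vector(sum_set, pt[1], pt[2])),
    unlist(field_vector(a_set, pt[1], pt[2])) +
      unlist(field_vector(b_set, pt[1], pt[2])),
    tolerance = 1e-10
  )
  # pure degree-3 set: |B| halves (n+2) = 5 times when r doubles
  deg3 <- gauss_coefficients(
    n = rep(3, 4), m = 0:3,
    g = c(100, 50, -30, 20), h = c(0, 10, 5, -8), epoch = 2020
  )
  b1 <- sqrt(sum(unlist(field_vector(deg3, 40, 70))^2))
  b2 <- sqrt(sum(unlist(field_vector(deg3, 40, 70, r = 2 * deg3$a))^2))
  expect_equal(b2 / b1, 0.5^5, tolerance = 1e-12)
})

test_that("declination and inclination follow their definitions", {
  ang <- field_angles(tibble::tibble(
    x_north = c(1, 0), y_east = c(0, 1), z_down = c(0, 1)
  ))
  expect_equal(ang$declination, c(0, 90))
  expect_equal(ang$inclination, c(0, 45))
  expect_error(
    field_angles(tibble::tibble(x_north = 0, y_east = 0, z_down = 10)),
    class = "circmag_undefined_declination"
  )
  expect_error(field_vector(dipole_set(), 90, 0),
    class = "circmag_pole_singularity"
  )
})

test_that("time propagation feeds through field evaluation", {
  set <- gauss_coefficients(
    n = 1, m = 0, g = -30000, h = 0, g_dot = 50, epoch = 2020
  )
  f0 <- field_vector(set, 0, 0, t = 2020)$x_north
  f5 <- field_vector(set, 0, 0, t = 2025)$x_north
  expect_equal(f5 - f0, -250, tolerance = 1e-9)
})

test_that("field_at augments a point table", {
  out <- field_at(
    tibble::tibble(lat = c(0, 30), lon = c(0, 50), time = 2020),
    dipole_set(earthlike = TRUE)
  )
  expect_true(all(c(
    "x_north", "y_east", "z_down", "h_intensity", "f_intensity",
    "declination", "inclination"
  ) %in% names(out)))
  expect_equal(out$declination, c(0, 0), tolerance = 1e-10)
  expect_equal(out$inclination[1], 0, tolerance = 1e-10)
})
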