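test_that("central angle reproduces known separations", {
  expect_equal(central_angle(12, 34, 12, 34), 0)
  expect_equal(central_angle(0, 0, 0, 90), pi / 2)
  # high-precision reference for (10N,20E) -> (30N,40E)
  expect_equal(central_angle(10, 20, 30, 40), 0.4772567600169833,
    tolerance = 1e-12
  )
})

test_that("central angle is symmetric, rotation-invariant and metric-like", {
  pts <- random_points(30, seed = 11)
  for (i in 1:10) {
    a <- pts[3 * i - 2, ]
    b <- pts[3 * i - 1, ]
    c <- pts[3 * i, ]
    ab <- central_angle(a$lat, a$lon, b$lat, b$lon)
    ba <- central_angle(b$lat, b$lon, a$lat, a$lon)
    expect_equal(ab, ba, tolerance = 1e-12)
    # triangle inequality
    bc <- central_angle(b$lat, b$lon, c$lat, c$lon)
    ac <- central_angle(a$lat, a$lon, c$lat, c$lon)
    expect_lte(ac, ab + bc + 1e-12)
    # shifting all longitudes leaves the separation unchanged
    expect_equal(
      central_angle(a$lat, a$lon + 77.7, b$lat, b$lon + 77.7), ab,
      tolerance = 1e-9
    )
  }
})

test_that("central angle rejects invalid coordinates", {
  expect_error(central_angle(NA, 0, 0, 0), class = "circmag_invalid_input")
  expect_error(central_angle(Inf, 0, 0, 0), class = "circmag_invalid_input")
  expect_error(central_angle(91, 0, 0, 0), class = "circmag_invalid_input")
})

test_that("initial bearing matches axial cases and a frozen reference", {
  expect_equal(initial_bearing(0, 0, 0, 10), pi / 2, tolerance = 1e-12)
  expect_equal(initial_bearing(0, 0, 10, 0), 0, tolerance = 1e-12)
  # (0,0) -> (45N,45E): atan2(cos 45, 1)
  expect_equal(initial_bearing(0, 0, 45, 45), 0.6154797086703873,
    tolerance = 1e-12
  )
})

test_that("bearing is consistent with great-circle advancement", {
  # advancing from p1 along the claimed bearing through the central
  # angle must land on p2 (independent of the bearing formula)
  pts <- random_points(40, seed = 23)
  for (i in 1:20) {
    p1 <- pts[2 * i - 1, ]
    p2 <- pts[2 * i, ]
    brg <- initial_bearing(p1$lat, p1$lon, p2$lat, p2$lon)
    ca <- central_angle(p1$lat, p1$lon, p2$lat, p2$lon)
    dest <- circmag:::gc_destination(p1$lat, p1$lon, brg, ca)
    expect_lt(
      central_angle(dest["lat"], dest["lon"], p2$lat, p2$lon), 1e-6
    )
  }
})

test_that("bearing agrees with a great-circle interpolation oracle", {
  pts <- random_points(40, seed = 31)
  for (i in 1:20) {
    p1 <- pts[i, ]
    p2 <- pts[20 + i, ]
    expect_angle_equal(
      initial_bearing(p1$lat, p1$lon, p2$lat, p2$lon),
      bearing_oracle(p1$lat, p1$lon, p2$lat, p2$lon),
      tol = 1e-6
    )
  }
})

test_that("bearing handles the antimeridian and rotational invariance", {
  b <- initial_bearing(10, 179, 10, -179)
  expect_lt(abs(b - pi / 2), 0.1) # short way: roughly due east
  pts <- random_points(20, seed = 7)
  p1 <- pts[1:10, ]
  p2 <- pts[11:20, ]
  expect_angle_equal(
    initial_bearing(p1$lat, p1$lon, p2$lat, p2$lon),
    initial_bearing(p1$lat, p1$lon + 123.4, p2$lat, p2$lon + 123.4),
    tol = 1e-9
  )
})

test_that("bearing is undefined for coincident points and pole starts", {
  expect_error(initial_bearing(10, 20, 10, 20),
    class = "circmag_undefined_bearing"
  )
  expect_error(initial_bearing(90, 0, 10, 20),
    class = "circmag_undefined_bearing"
  )
})

test_that("direction series handles bearings and turn angles", {
  trk <- equatorial_track(3)
  ds <- direction_series(trk, mode = "bearing")
  expect_equal(nrow(ds), 2)
  expect_equal(ds$theta, c(pi / 2, pi / 2), tolerance = 1e-9)
  dt <- direction_series(trk, mode = "turn_angle")
  expect_equal(nrow(dt), 1)
  expect_equal(dt$theta, 0, tolerance = 1e-9)
  # turn angle anchored at the interior vertex
  expect_equal(dt$lon, trk$lon[2])
})

test_that("direction series matches a brute-force bearing loop", {
  trk <- simulate_track_vm(n_points = 50, seed = 13)
  ds <- direction_series(trk)
  manual <- vapply(seq_len(nrow(trk) - 1), function(i) {
    initial_bearing(
      trk$lat[i], trk$lon[i], trk$lat[i + 1], trk$lon[i + 1]
    )
  }, numeric(1))
  expect_equal(ds$theta, manual, tolerance = 1e-12)
})

test_that("repeated positions are dropped with a warning", {
  trk <- equatorial_track(4)
  trk$lat[3] <- trk$lat[2]
  trk$lon[3] <- trk$lon[2]
  expect_warning(
    ds <- direction_series(trk),
    "repeated position"
  )
  expect_equal(nrow(ds), 2)
})

test_that("too-short tracks and unordered timestamps error", {
  expect_error(
    direction_series(equatorial_track(1)),
    class = "circmag_too_short_track"
  )
  expect_error(
    direction_series(equatorial_track(2), mode = "turn_angle"),
    class = "circmag_too_short_track"
  )
  trk <- equatorial_track(3)
  trk$timestamp[2] <- trk$timestamp[1]
  expect_error(direction_series(trk), class = "circmag_invalid_input")
})

test_that("row order does not matter", {
  trk <- simulate_track_vm(n_points = 30, seed = 3)
  shuffled <- trk[withr::with_seed(1, sample(nrow(trk))), ]
  expect_equal(
    direction_series(trk)$theta,
    direction_series(shuffled)$theta
  )
})
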