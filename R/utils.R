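# Angle helpers. Geographic coordinates cross the package boundary in
# degrees; every angle handed to the circular-statistics layer is in
# radians. These helpers are the only place wrapping conventions live.

#' Wrap angles onto the circle
#'
#' `wrap_2pi()` maps angles to `[0, 2*pi)`; `wrap_pi()` maps angular
#' differences to `(-pi, pi]`, the convention used for turn angles,
#' antimeridian-safe longitude differences and covariate deltas.
#'
#' @param x Numeric vector of angles in radians.
#' @return Numeric vector of wrapped angles.
#' @examples
#' wrap_2pi(-pi / 2)
#' wrap_pi(3 * pi / 2)
#' @export
wrap_2pi <- function(x) {
  out <- x %% (2 * pi)
  # guard against 2*pi itself from floating-point roundoff
  out[out >= 2 * pi] <- 0
  out
}

#' @rdname wrap_2pi
#' @export
wrap_pi <- function(x) {
  out <- (x + pi) %% (2 * pi) - pi
  out[out <= -pi] <- pi
  out
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Normalize longitudes to [-180, 180)
norm_lon <- function(lon) {
  out <- (lon + 180) %% 360 - 180
  out[out >= 180] <- -180
  out
}

abort_circmag <- function(message, class, ...) {
  abort(message, class = c(paste0("circmag_", class), "circmag_error"), ...)
}

check_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort_circmag(
      paste0("`", what, "` must be finite and numeric."),
      "invalid_input"
    )
  }
  invisible(x)
}

# Resultant length of a circular sample, in [0, 1]
resultant_length <- function(theta) {
  sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
}

# Deterministic child-seed derivation: one master seed fans out to
# per-(unit, stage) streams so each stage is independently reproducible.
# Kept below 2^31 - 1 so the value is a valid R integer seed.
child_seed <- function(master, unit = 0L, stage = 0L) {
  as.integer((as.numeric(master) + 7919 * unit + 104729 * stage) %%
    (.Machine$integer.max - 1L))
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
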