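#' Trigonometric-polynomial design matrix
#'
#' Columns `1, cos(alpha), sin(alpha), ..., cos(m alpha), sin(m alpha)`
#' shared by the two linear models of circular-circular regression. The
#' identically-zero `sin(0 alpha)` column is omitted, so the matrix has
#' `2m + 1` columns.
#'
#' @param alpha Covariate angles in radians.
#' @param degree Polynomial degree `m >= 1`.
#' @return An `n x (2m + 1)` matrix.
#' @export
circ_design <- function(alpha, degree = 1) {
  if (degree < 1) abort_circmag("`degree` must be >= 1.", "invalid_input")
  n <- length(alpha)
  if (n < 2 * degree + 1) {
    abort_circmag(
      "Need at least 2*degree + 1 observations for the design.",
      "underdetermined_design"
    )
  }
  cols <- c(list(rep(1, n)), lapply(seq_len(degree), function(k) {
    cbind(cos(k * alpha), sin(k * alpha))
  }))
  x <- do.call(cbind, cols)
  colnames(x) <- c(
    "(Intercept)",
    as.vector(rbind(
      paste0("cos", seq_len(degree), "a"),
      paste0("sin", seq_len(degree), "a")
    ))
  )
  x
}

#' Circular-circular regression via trigonometric polynomials
#'
#' Models the conditional expectation of the unit vector of the
#' response `beta` given a circular covariate `alpha`:
#' `E(cos beta | alpha)` and `E(sin beta | alpha)` are each approximated
#' by a trigonometric polynomial of degree `m` and fitted by ordinary
#' least squares on the shared design matrix of [circ_design()]. The
#' predicted direction is the quadrant-aware angle of the fitted vector,
#' and the residual pair `(eps1, eps2)` summarises the angular error; a
#' von Mises angular error of concentration `kappa` shrinks the fitted
#' vector length by the factor `A1(kappa) = I_1/I_0(kappa)`, so the
#' estimated coefficients approach the `A1`-shrunk versions of any
#' generative ones.
#'
#' @param alpha Covariate angles, radians.
#' @param beta Response angles, radians.
#' @param degree Trigonometric polynomial degree `m` (default 1, the
#'   smallest model; see [select_degree()] for data-driven choice).
#' @param covariate_label Optional label carried through to summaries.
#' @return An object of class `circmag_circ_reg` with components
#'   `coef_cos` and `coef_sin` (named coefficient vectors of the cosine
#'   and sine models), `sigma` (the 2x2 residual dispersion matrix),
#'   `rho_model` (circular correlation between observed and fitted
#'   response), `degree`, `n`, `rss` and the data used.
#' @examples
#' a <- vm_sample(200, 3, 0.5, seed = 2)
#' fit <- circ_reg(a, wrap_2pi(a + pi / 4))
#' tidy(fit)
#' @export
circ_reg <- function(alpha, beta, degree = 1, covariate_label = NA) {
  if (length(alpha) != length(beta)) {
    abort_circmag("`alpha` and `beta` must have equal length.",
      "invalid_input"
    )
  }
  n <- length(alpha)
  if (n < 2 * degree + 2) {
    abort_circmag(
      "Need at least 2*degree + 2 observations to fit.",
      "underdetermined_design"
    )
  }
  x <- circ_design(alpha, degree)
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    abort_circmag(
      "Design matrix is rank deficient (degenerate covariate).",
      "degenerate_covariate"
    )
  }
  y <- cbind(cos(beta), sin(beta))
  cf <- qr.coef(qr_x, y)
  resid <- y - x %*% cf
  fit <- structure(
    list(
      coef_cos = stats::setNames(cf[, 1], colnames(x)),
      coef_sin = stats::setNames(cf[, 2], colnames(x)),
      sigma = crossprod(resid) / n,
      degree = degree, n = n,
      rss = sum(resid^2),
      alpha = alpha, beta = beta,
      covariate_label = covariate_label
    ),
    class = "circmag_circ_reg"
  )
  fit$rho_model <- model_rho(fit)
  fit
}

#' Predicted direction from a circular-circular regression
#'
#' Evaluates the two fitted trigonometric polynomials `g1` and `g2` at
#' the new covariate values and returns the quadrant-aware direction
#' `atan2(g2, g1)` wrapped to `[0, 2*pi)`.
#'
#' @param object A [circ_reg()] fit.
#' @param newdata Covariate angles in radians; defaults to the training
#'   values.
#' @param ... Unused.
#' @return Predicted response angles in `[0, 2*pi)`.
#' @export
predict.circmag_circ_reg <- function(object, newdata = NULL, ...) {
  alpha <- newdata %||% object$alpha
  x <- circ_design_unchecked(alpha, object$degree)
  g1 <- drop(x %*% object$coef_cos)
  g2 <- drop(x %*% object$coef_sin)
  if (any(abs(g1) < 1e-12 & abs(g2) < 1e-12)) {
    abort_circmag(
      "Predicted direction undefined: fitted vector has zero length.",
      "undefined_direction"
    )
  }
  wrap_2pi(atan2(g2, g1))
}

# design without the n >= 2m+1 check, for prediction at few points
circ_design_unchecked <- function(alpha, degree) {
  n <- length(alpha)
  cols <- c(list(rep(1, n)), lapply(seq_len(degree), function(k) {
    cbind(cos(k * alpha), sin(k * alpha))
  }))
  do.call(cbind, cols)
}

#' Model association of a circular regression
#'
#' The single-number association reported for a fit: the
#' circular-circular correlation ([circ_corr()]) between the observed
#' response and the fitted directions. Recomputed on new data when
#' `alpha` and `beta` are supplied.
#'
#' @param fit A [circ_reg()] object.
#' @param alpha,beta Optional new covariate/response angles.
#' @return A number in `[-1, 1]`.
#' @export
model_rho <- function(fit, alpha = NULL, beta = NULL) {
  stopifnot(inherits(fit, "circmag_circ_reg"))
  alpha <- alpha %||% fit$alpha
  beta <- beta %||% fit$beta
  circ_corr(beta, predict(fit, alpha))
}

#' Data-driven degree for circular-circular regression
#'
#' Chooses the trigonometric polynomial degree minimising a BIC-like
#' criterion: the mean squared residual of the two linear models plus a
#' penalty `2 (2m + 1) log(n) / n` (one `(2m + 1) log(n) / n` share per
#' model). Ties break toward the smaller degree.
#'
#' @inheritParams circ_reg
#' @param m_max Largest degree considered.
#' @return The selected degree, an integer with the criterion table in
#'   attribute `"criteria"`.
#' @export
select_degree <- function(alpha, beta, m_max = 3) {
  if (m_max < 1) abort_circmag("`m_max` must be >= 1.", "invalid_input")
  n <- length(alpha)
  if (n < 2 * m_max + 2) {
    abort_circmag(
      "Need at least 2*m_max + 2 observations.",
      "underdetermined_design"
    )
  }
  crit <- vapply(seq_len(m_max), function(m) {
    fit <- circ_reg(alpha, beta, degree = m)
    fit$rss / n + 2 * (2 * m + 1) * log(n) / n
  }, numeric(1))
  chosen <- which.min(crit) # which.min takes the first (smallest m) tie
  structure(as.integer(chosen),
    criteria = tibble(degree = seq_len(m_max), criterion = crit)
  )
}

#' @export
print.circmag_circ_reg <- function(x, ...) {
  cat(sprintf(
    "Circular-circular regression (degree %d, n = %d)%s\nrho_model = %.4f\n",
    x$degree, x$n,
    if (is.na(x$covariate_label)) "" else
      paste0(" [", x$covariate_label, "]"),
    x$rho_model
  ))
  cat("cosine model:\n")
  print(round(x$coef_cos, 4))
  cat("sine model:\n")
  print(round(x$coef_sin, 4))
  invisible(x)
}

#' @export
tidy.circmag_circ_reg <- function(x, ...) {
  tibble(
    term = names(x$coef_cos),
    cos_coef = unname(x$coef_cos),
    sin_coef = unname(x$coef_sin)
  )
}

#' @export
glance.circmag_circ_reg <- function(x, ...) {
  tibble(
    degree = x$degree, n = x$n, rho_model = x$rho_model,
    rss = x$rss,
    sigma11 = x$sigma[1, 1], sigma22 = x$sigma[2, 2],
    sigma12 = x$sigma[1, 2]
  )
}

#' @export
autoplot.circmag_circ_reg <- function(object, ...) {
  tib <- tibble(
    alpha = wrap_2pi(object$alpha),
    observed = wrap_2pi(object$beta),
    fitted = predict(object)
  )
  tib <- tidyr_longer(tib)
  ggplot2::ggplot(
    tib,
    ggplot2::aes(x = .data$alpha, y = .data$value, colour = .data$series)
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::coord_cartesian(xlim = c(0, 2 * pi), ylim = c(0, 2 * pi)) +
    ggplot2::labs(
      x = "covariate angle (rad)", y = "response angle (rad)",
      colour = NULL,
      title = sprintf(
        "Circular-circular regression, degree %d, rho = %.3f",
        object$degree, object$rho_model
      )
    )
}

# minimal long-format pivot (avoids importing tidyr for one call)
tidyr_longer <- function(tib) {
  dplyr::bind_rows(
    tibble(alpha = tib$alpha, series = "observed", value = tib$observed),
    tibble(alpha = tib$alpha, series = "fitted", value = tib$fitted)
  )
}
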