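#' Watson's U-squared statistic from probability integral transforms
#'
#' Given values `u = F0(theta)` of a hypothesised distribution function
#' at the sample angles, computes
#' `W^2 = sum_i ((u_(i) - (2i-1)/(2n)) - (ubar - 1/2))^2 + 1/(12n)`.
#' When the order statistics sit exactly at the midpoints `(i-1/2)/n`
#' the sum vanishes and `W^2 = 1/(12n)`, its lower bound.
#'
#' @param u Probability integral transforms in `[0, 1]`; sorted
#'   internally (stable, ties kept).
#' @return The statistic, a single number `>= 1/(12n)` up to rounding.
#' @export
watson_statistic <- function(u) {
  n <- length(u)
  u <- sort(u, method = "radix")
  i <- seq_len(n)
  dev <- u - (2 * i - 1) / (2 * n)
  sum((dev - (mean(u) - 0.5))^2) + 1 / (12 * n)
}

# statistic across rows of a sorted-U matrix
watson_statistic_rows <- function(u_sorted) {
  n <- ncol(u_sorted)
  mid <- (2 * seq_len(n) - 1) / (2 * n)
  dev <- sweep(u_sorted, 2, mid) - (rowMeans(u_sorted) - 0.5)
  rowSums(dev^2) + 1 / (12 * n)
}

row_sort <- function(mat) {
  matrix(mat[order(row(mat), mat)], nrow(mat), ncol(mat), byrow = TRUE)
}

#' Watson's U-squared goodness-of-fit test for circular data
#'
#' Rotation-invariant Cramer-von Mises-type test of a circular sample
#' against the circular uniform distribution
#' (`variant = "uniformity"`) or against a von Mises distribution with
#' parameters estimated from the sample
#' (`variant = "vonmises_estimated"`). Critical values are computed by
#' seeded Monte Carlo rather than read from printed tables: plain
#' simulation under uniformity, and a parametric bootstrap with
#' re-estimation under the composite von Mises null, so the effect of
#' estimating `(mu, kappa)` is reflected in the null distribution.
#'
#' @param theta Angles in radians, `n >= 8`.
#' @param variant `"vonmises_estimated"` (default) or `"uniformity"`.
#' @param alpha Significance level for the critical value.
#' @param n_boot Monte Carlo / bootstrap replicates.
#' @param seed Optional integer seed for the critical-value simulation.
#' @return An object of class `circmag_watson` with elements
#'   `statistic`, `critical_value`, `reject`, `variant`, `alpha`, `n`,
#'   `n_boot` and, for the estimated variant, the fitted `mu` and
#'   `kappa`.
#' @examples
#' x <- vm_sample(100, mu = 1, kappa = 2, seed = 7)
#' watson_u2(x, n_boot = 200, seed = 1)
#' @export
watson_u2 <- function(theta, variant = c("vonmises_estimated", "uniformity"),
                      alpha = 0.05, n_boot = 1000, seed = NULL) {
  variant <- rlang::arg_match(variant)
  n <- length(theta)
  if (n < 8) {
    abort_circmag("Watson's test needs at least 8 observations.",
      "too_few_observations"
    )
  }
  theta <- wrap_2pi(theta)
  if (variant == "uniformity") {
    u_obs <- sort(theta / (2 * pi))
    stat <- watson_statistic(u_obs)
    null_stats <- with_seed_if(seed, {
      u <- matrix(runif(n_boot * n), n_boot, n)
      watson_statistic_rows(row_sort(u))
    })
    fit <- NULL
  } else {
    fit <- vm_mle(theta)
    u_obs <- vm_cdf(sort(theta), fit$mu, fit$kappa)
    stat <- watson_statistic(u_obs)
    null_stats <- with_seed_if(seed, {
      boot <- rvm_matrix(n_boot, n, fit$mu, fit$kappa)
      boot <- row_sort(boot)
      refit <- vm_mle_rows(boot)
      u <- vm_cdf_rows(boot, refit$mu, refit$kappa)
      watson_statistic_rows(u)
    })
  }
  crit <- unname(quantile(null_stats, 1 - alpha, names = FALSE))
  structure(
    list(
      statistic = stat, critical_value = crit, reject = stat > crit,
      variant = variant, alpha = alpha, n = n, n_boot = n_boot,
      mu = fit$mu, kappa = fit$kappa, u = u_obs
    ),
    class = "circmag_watson"
  )
}

#' @export
print.circmag_watson <- function(x, ...) {
  cat(sprintf(
    "Watson U2 test (%s)\nU2 = %.5f, critical value (alpha = %.3g, %d MC reps) = %.5f\n%s\n",
    x$variant, x$statistic, x$alpha, x$n_boot, x$critical_value,
    if (x$reject) "Reject the null distribution." else
      "Do not reject the null distribution."
  ))
  invisible(x)
}

#' @export
tidy.circmag_watson <- function(x, ...) {
  tibble(
    statistic = x$statistic, critical_value = x$critical_value,
    reject = x$reject, variant = x$variant, alpha = x$alpha, n = x$n
  )
}

#' @export
autoplot.circmag_watson <- function(object, ...) {
  # empirical distribution of the probability integral transforms
  # against the 45-degree reference line of a perfect fit
  n <- object$n
  tib <- tibble(u = object$u, edf = seq_len(n) / n)
  ggplot2::ggplot(tib, ggplot2::aes(x = .data$u, y = .data$edf)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(
      slope = 1, intercept = 0,
      linetype = 2, colour = "grey50"
    ) +
    ggplot2::labs(
      x = "null probability integral transform",
      y = "empirical distribution",
      title = sprintf(
        "Watson U2 = %.4f (%s), n = %d", object$statistic,
        object$variant, n
      )
    )
}
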