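#' Plot a track in longitude-latitude space
#'
#' Simple path plot of one or more species' tracks, coloured by
#' species. Intended for quick inspection, not cartography: no map
#' projection or coastline is drawn.
#'
#' @param tracks A track tibble (`species`, `lat`, `lon`).
#' @return A ggplot object.
#' @export
plot_track <- function(tracks) {
  ggplot2::ggplot(
    tracks,
    ggplot2::aes(x = .data$lon, y = .data$lat, colour = .data$species)
  ) +
    ggplot2::geom_path(alpha = 0.8) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::labs(x = "longitude (deg)", y = "latitude (deg)")
}

#' Rose diagram of a circular sample
#'
#' Circular histogram of angles (bearings, turn angles or covariate
#' angles), with north at the top and angles increasing clockwise, the
#' compass convention used for bearings.
#'
#' @param theta Angles in radians.
#' @param bins Number of sectors.
#' @return A ggplot object.
#' @export
plot_rose <- function(theta, bins = 36) {
  tib <- tibble(theta_deg = rad2deg(wrap_2pi(theta)))
  ggplot2::ggplot(tib, ggplot2::aes(x = .data$theta_deg)) +
    ggplot2::geom_histogram(
      breaks = seq(0, 360, length.out = bins + 1),
      fill = "steelblue", colour = "white", linewidth = 0.2
    ) +
    ggplot2::coord_polar(start = 0, direction = 1) +
    ggplot2::scale_x_continuous(
      limits = c(0, 360),
      breaks = c(0, 90, 180, 270),
      labels = c("N", "E", "S", "W")
    ) +
    ggplot2::labs(x = NULL, y = "count")
}

#' Plot per-species correlation results
#'
#' Dot plot of the circular correlation estimates from
#' [run_analysis()], one panel per covariate, with significant results
#' (at the configured level) highlighted.
#'
#' @param results Tibble from [run_analysis()].
#' @return A ggplot object.
#' @export
plot_results <- function(results) {
  cfg <- attr(results, "config")
  alpha <- if (!is.null(cfg)) cfg$alpha else 0.05
  long <- dplyr::bind_rows(
    tibble(
      species = results$species, covariate = "inclination",
      r = results$r_inclination, p = results$p_inclination
    ),
    tibble(
      species = results$species, covariate = "declination",
      r = results$r_declination, p = results$p_declination
    )
  )
  long$significant <- !is.na(long$p) & long$p < alpha
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$r, y = .data$species,
      colour = .data$significant
    )
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~covariate) +
    ggplot2::labs(
      x = "circular correlation r", y = NULL,
      colour = paste0("p < ", alpha)
    )
}
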