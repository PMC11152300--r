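#' Decimal year of a calendar instant
#'
#' Year plus the elapsed fraction of that year (leap years honoured),
#' the time convention of secular-variation propagation. Accepts
#' POSIXct/Date vectors, ISO-8601 character strings, or numerics
#' (returned unchanged, assumed already decimal years).
#'
#' @param x Date-times in any of the accepted forms.
#' @return Numeric decimal years.
#' @examples
#' decimal_year("2023-01-01T00:00:00Z") # 2023
#' decimal_year("2024-12-31T00:00:00Z") # 2024 + 365/366
#' @export
decimal_year <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.character(x) || is.factor(x)) {
    parsed <- suppressWarnings(
      lubridate::parse_date_time(
        as.character(x),
        orders = c("Ymd HMS", "Ymd HM", "Ymd", "Ymd HMOS"),
        tz = "UTC", quiet = TRUE
      )
    )
    if (anyNA(parsed) & !anyNA(x)) {
      bad <- which(is.na(parsed) & !is.na(x))
      abort_circmag(
        paste0(
          "Unparseable timestamp(s) at position(s): ",
          paste(head(bad, 5), collapse = ", ")
        ),
        "format"
      )
    }
    x <- parsed
  }
  lubridate::decimal_date(x)
}

#' Read a track table from CSV
#'
#' Reads a Movebank-style CSV, maps the configured columns onto the
#' package's canonical track layout, groups rows by species and sorts
#' them by timestamp. Exact duplicate rows are dropped (with a count
#' reported); rows with out-of-range coordinates or unparseable
#' timestamps are rejected one by one with their line numbers.
#'
#' @param path CSV file path.
#' @param column_map Named character vector mapping the canonical names
#'   `species`, `timestamp`, `lat`, `lon` to the file's column names.
#'   Defaults to the Movebank dialect
#'   (`species`, `timestamp`, `location-lat`, `location-long`).
#' @return A tibble with columns `species`, `timestamp` (POSIXct),
#'   `time` (decimal year), `lat`, `lon`, sorted by species and time.
#' @export
read_tracks <- function(path, column_map = NULL) {
  column_map <- column_map %||% c(
    species = "species", timestamp = "timestamp",
    lat = "location-lat", lon = "location-long"
  )
  if (!file.exists(path)) abort_circmag(paste0("No such file: ", path), "io")
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) abort_circmag("Track file is empty.", "empty_input")
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols) > 0) {
    abort_circmag(
      paste0(
        "Mapped column(s) absent from file: ",
        paste(missing_cols, collapse = ", ")
      ),
      "schema"
    )
  }
  df <- tibble(
    species = as.character(raw[[column_map[["species"]]]]),
    timestamp_raw = raw[[column_map[["timestamp"]]]],
    lat = as.numeric(raw[[column_map[["lat"]]]]),
    lon = as.numeric(raw[[column_map[["lon"]]]]),
    line = seq_len(nrow(raw)) + 1L # header is line 1
  )
  dup <- duplicated(df[, c("species", "timestamp_raw", "lat", "lon")])
  if (any(dup)) {
    inform(paste0("Dropped ", sum(dup), " exact duplicate row(s)."))
    df <- df[!dup, , drop = FALSE]
  }
  ts <- suppressWarnings(
    lubridate::parse_date_time(
      as.character(df$timestamp_raw),
      orders = c("Ymd HMS", "Ymd HM", "Ymd", "Ymd HMOS"),
      tz = "UTC", quiet = TRUE
    )
  )
  bad <- is.na(ts) | is.na(df$lat) | is.na(df$lon) |
    abs(df$lat) > 90 | !is.finite(df$lon)
  if (any(bad)) {
    warn(paste0(
      "Rejected ", sum(bad), " invalid row(s) at line(s): ",
      paste(head(df$line[bad], 10), collapse = ", ")
    ))
    df <- df[!bad, , drop = FALSE]
    ts <- ts[!bad]
  }
  if (nrow(df) == 0) abort_circmag("No valid rows remain.", "empty_input")
  out <- tibble(
    species = df$species,
    timestamp = ts,
    time = lubridate::decimal_date(ts),
    lat = df$lat,
    lon = norm_lon(df$lon)
  )
  dplyr::arrange(out, .data$species, .data$time)
}

#' Magnetic covariate series aligned to a direction series
#'
#' Evaluates declination or inclination along a single-species track
#' and aligns it with the bearing series of [direction_series()]:
#' `mode = "point"` returns the field angle at each segment's start
#' point and time; `mode = "delta"` (the pipeline default) returns the
#' wrapped change of the angle across each segment. Either way the
#' series has one value per segment and is expressed in radians for the
#' circular-statistics layer.
#'
#' @param track A single-species track tibble (columns `lat`, `lon` and
#'   `time` or `timestamp`).
#' @param coeffs A [gauss_coefficients()] object.
#' @param mode `"delta"` or `"point"`.
#' @param covariate `"inclination"` or `"declination"`.
#' @return Numeric vector of angles in radians, length `nrow(track) - 1`.
#' @export
magnetic_covariates <- function(track, coeffs,
                                mode = c("delta", "point"),
                                covariate = c(
                                  "inclination",
                                  "declination"
                                )) {
  mode <- rlang::arg_match(mode)
  covariate <- rlang::arg_match(covariate)
  n <- nrow(track)
  if (n < 2) abort_circmag("Track needs at least 2 points.", "invalid_input")
  t <- if ("time" %in% names(track)) {
    track$time
  } else {
    decimal_year(track$timestamp)
  }
  angles_deg <- tryCatch(
    field_angles(
      field_vector(coeffs, track$lat, track$lon, t = t)
    )[[covariate]],
    circmag_error = function(e) {
      abort_circmag(
        paste0("Field evaluation failed along the track: ",
          conditionMessage(e)
        ),
        "covariate", parent = e
      )
    }
  )
  ang <- deg2rad(angles_deg)
  if (mode == "point") {
    ang[-n]
  } else {
    wrap_pi(diff(ang))
  }
}

#' Analysis configuration
#'
#' Resolved settings for [run_analysis()], with the defaults the
#' package runs under: bearings as the direction variable, field-change
#' (`delta`) covariates, Watson test of the estimated von Mises null,
#' and a master seed from which all per-species Monte Carlo streams are
#' derived.
#'
#' @param direction_mode `"bearing"` or `"turn_angle"` for
#'   [direction_series()].
#' @param covariate_mode `"delta"` or `"point"` for
#'   [magnetic_covariates()].
#' @param covariates Character vector of covariates to test.
#' @param alpha Significance level shared by all tests.
#' @param watson_variant Variant for [watson_u2()].
#' @param n_boot Monte Carlo replicates for Watson critical values.
#' @param min_segments Minimum direction-series length for a species to
#'   be analysed rather than skipped.
#' @param degree Trigonometric degree for [circ_reg()].
#' @param seed Master integer seed; per-species child seeds are derived
#'   deterministically from it.
#' @return A list of class `circmag_config`.
#' @export
analysis_config <- function(direction_mode = "bearing",
                            covariate_mode = "delta",
                            covariates = c("inclination", "declination"),
                            alpha = 0.05,
                            watson_variant = "vonmises_estimated",
                            n_boot = 500, min_segments = 30,
                            degree = 1, seed = 1) {
  structure(
    list(
      direction_mode = direction_mode, covariate_mode = covariate_mode,
      covariates = covariates, alpha = alpha,
      watson_variant = watson_variant, n_boot = n_boot,
      min_segments = min_segments, degree = degree, seed = seed
    ),
    class = "circmag_config"
  )
}

#' Read an analysis configuration from YAML or JSON
#'
#' Keys absent from the file keep their [analysis_config()] defaults.
#'
#' @param path YAML (or JSON) configuration file.
#' @return A `circmag_config` list.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    warn(paste0(
      "Ignoring unknown config key(s): ", paste(unknown, collapse = ", ")
    ))
    vals <- vals[intersect(names(vals), known)]
  }
  do.call(analysis_config, vals)
}

#' Run the full per-species analysis
#'
#' For every species in `tracks`: build the direction series, test its
#' distribution with Watson's U-squared, and for each magnetic
#' covariate run the circular-circular correlation test and the
#' circular-circular regression. Species with fewer segments than
#' `min_segments` are skipped with a recorded reason; covariates that
#' turn out degenerate (for example declination under a purely axial
#' dipole field) are recorded as skipped for that species rather than
#' aborting the run. Fully deterministic given the master seed.
#'
#' @param tracks Track tibble as returned by [read_tracks()] or the
#'   simulators (several species allowed).
#' @param coeffs A [gauss_coefficients()] object.
#' @param config An [analysis_config()] list.
#' @return A tibble with one row per species: segment counts, the
#'   Watson statistic and critical value, and `r`, `z`, `p` and
#'   `rho_model` per covariate, plus a `skip_reason` column. The
#'   resolved configuration is attached as attribute `"config"`.
#' @export
run_analysis <- function(tracks, coeffs, config = analysis_config()) {
  stopifnot(inherits(coeffs, "gauss_coef"))
  species_list <- sort(unique(tracks$species))
  if (length(species_list) == 0) {
    abort_circmag("No species in input.", "empty_result")
  }
  rows <- purrr::imap(species_list, function(sp, idx) {
    trk <- dplyr::filter(tracks, .data$species == sp)
    analyse_species(trk, sp, idx, coeffs, config)
  })
  out <- dplyr::bind_rows(rows)
  if (all(is.na(out$watson_u2))) {
    abort_circmag("No species could be analysed.", "empty_result")
  }
  attr(out, "config") <- config
  out
}

# one species worth of pipeline; returns a one-row tibble
analyse_species <- function(trk, sp, idx, coeffs, config) {
  skeleton <- tibble(
    species = sp, n_segments = NA_integer_,
    watson_u2 = NA_real_, watson_critical = NA_real_,
    watson_reject = NA,
    r_inclination = NA_real_, z_inclination = NA_real_,
    p_inclination = NA_real_, rho_inclination = NA_real_,
    r_declination = NA_real_, z_declination = NA_real_,
    p_declination = NA_real_, rho_declination = NA_real_,
    degree = NA_integer_, skip_reason = NA_character_
  )
  ds <- tryCatch(
    direction_series(trk, mode = config$direction_mode),
    circmag_error = function(e) e
  )
  if (inherits(ds, "error")) {
    skeleton$skip_reason <- conditionMessage(ds)
    return(skeleton)
  }
  n_seg <- nrow(ds)
  skeleton$n_segments <- n_seg
  if (n_seg < config$min_segments) {
    skeleton$skip_reason <- paste0(
      "Only ", n_seg, " segments (minimum ", config$min_segments, ")."
    )
    return(skeleton)
  }
  theta <- ds$theta
  # the deduplicated, time-sorted track the direction series was built
  # from, so covariate and direction series stay aligned segment-wise
  trk_sorted <- trk
  trk_sorted$time <- decimal_year(trk_sorted$timestamp)
  trk_sorted <- drop_repeated_points(
    trk_sorted[order(trk_sorted$time), , drop = FALSE]
  )

  wat <- watson_u2(
    theta,
    variant = config$watson_variant, alpha = config$alpha,
    n_boot = config$n_boot,
    seed = child_seed(config$seed, idx, 1L)
  )
  skeleton$watson_u2 <- wat$statistic
  skeleton$watson_critical <- wat$critical_value
  skeleton$watson_reject <- wat$reject
  skeleton$degree <- as.integer(config$degree)

  for (cov in config$covariates) {
    res <- tryCatch(
      {
        m <- magnetic_covariates(
          trk_sorted, coeffs,
          mode = config$covariate_mode, covariate = cov
        )
        # turn angles live on interior vertices: align to the
        # outgoing segment of each vertex
        if (config$direction_mode == "turn_angle") m <- m[-1]
        ct <- circ_corr_test(theta, m,
          alpha = config$alpha,
          covariate_label = cov
        )
        fit <- circ_reg(m, theta,
          degree = config$degree,
          covariate_label = cov
        )
        list(ct = ct, fit = fit)
      },
      circmag_error = function(e) e
    )
    if (inherits(res, "error")) {
      note <- paste0(cov, ": ", conditionMessage(res))
      skeleton$skip_reason <- if (is.na(skeleton$skip_reason)) {
        note
      } else {
        paste(skeleton$skip_reason, note, sep = " | ")
      }
      next
    }
    skeleton[[paste0("r_", cov)]] <- res$ct$r
    skeleton[[paste0("z_", cov)]] <- res$ct$statistic
    skeleton[[paste0("p_", cov)]] <- res$ct$p_value
    skeleton[[paste0("rho_", cov)]] <- res$fit$rho_model
  }
  skeleton
}

#' Write (and read back) analysis results
#'
#' `format = "csv"` writes the flat per-species table;
#' `format = "json"` additionally embeds the resolved configuration
#' (including the master seed) so a results file is self-describing and
#' byte-reproducible given the same inputs.
#'
#' @param results Tibble from [run_analysis()].
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("csv", "json")) {
  format <- rlang::arg_match(format)
  if (nrow(results) == 0) abort_circmag("Empty results.", "empty_result")
  if (format == "csv") {
    readr::write_csv(results, path)
  } else {
    cfg <- attr(results, "config")
    jsonlite::write_json(
      list(config = unclass(cfg), results = results),
      path,
      auto_unbox = TRUE, digits = NA, null = "null", na = "null"
    )
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path, format = c("csv", "json")) {
  format <- rlang::arg_match(format)
  if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
    out <- as_tibble(parsed$results)
    attr(out, "config") <- parsed$config
    out
  }
}
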