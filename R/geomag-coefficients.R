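#' Gauss coefficient sets
#'
#' A `gauss_coef` object holds the Schmidt semi-normalised
#' spherical-harmonic (Gauss) coefficients of the main geomagnetic field:
#' `g`/`h` in nT at a reference epoch, their linear secular-variation
#' rates `g_dot`/`h_dot` in nT/yr, and optional quadratic terms
#' `g_ddot`/`h_ddot` in nT/yr^2. Degree `n` runs from 1 to `n_max`,
#' order `m` from 0 to `n`; `h` terms with `m = 0` are identically zero
#' by convention.
#'
#' @param n,m Integer vectors of degree and order, one entry per
#'   coefficient pair.
#' @param g,h Main-field coefficients, nT.
#' @param g_dot,h_dot Secular-variation rates, nT/yr (default 0).
#' @param g_ddot,h_ddot Optional quadratic rates, nT/yr^2. `NULL` means
#'   absent (treated as 0).
#' @param epoch Reference epoch `t0` as a decimal year.
#' @param model_name Short label stored in the file header.
#' @param n_max Truncation degree; defaults to `max(n)`.
#' @param a Geomagnetic reference radius in metres (6371200 by default).
#' @return An object of class `gauss_coef`.
#' @seealso [read_cof()], [write_cof()], [coefficients_at_time()],
#'   [field_vector()]
#' @examples
#' dip <- gauss_coefficients(n = 1, m = 0, g = -30000, h = 0, epoch = 2020)
#' tidy(dip)
#' @export
gauss_coefficients <- function(n, m, g, h, g_dot = 0, h_dot = 0,
                               g_ddot = NULL, h_ddot = NULL,
                               epoch, model_name = "SYNTH",
                               n_max = max(n), a = 6371200) {
  n <- as.integer(n)
  m <- as.integer(m)
  k <- length(n)
  coef <- tibble(
    n = n, m = m,
    g = rep_len(as.numeric(g), k), h = rep_len(as.numeric(h), k),
    g_dot = rep_len(as.numeric(g_dot), k),
    h_dot = rep_len(as.numeric(h_dot), k),
    g_ddot = rep_len(as.numeric(g_ddot %||% 0), k),
    h_ddot = rep_len(as.numeric(h_ddot %||% 0), k)
  )
  if (any(coef$n < 1) || any(coef$m < 0) || any(coef$m > coef$n)) {
    abort_circmag(
      "Need 1 <= n and 0 <= m <= n for every coefficient.",
      "format"
    )
  }
  if (anyDuplicated(coef[, c("n", "m")])) {
    abort_circmag("Duplicate (n, m) coefficient pair.", "format")
  }
  if (any(coef$h[coef$m == 0] != 0) || any(coef$h_dot[coef$m == 0] != 0)) {
    abort_circmag("h coefficients with m = 0 must be zero.", "format")
  }
  if (n_max < max(coef$n)) {
    abort_circmag("`n_max` is smaller than the largest degree given.",
      "format"
    )
  }
  coef <- coef[order(coef$n, coef$m), , drop = FALSE]
  out <- structure(
    list(
      coef = coef,
      epoch = as.numeric(epoch),
      model_name = as.character(model_name),
      n_max = as.integer(n_max),
      a = as.numeric(a),
      has_quadratic = !is.null(g_ddot) || !is.null(h_ddot)
    ),
    class = "gauss_coef"
  )
  # dense matrix layout cached once; evaluation code is loop-heavy
  out$mats <- coef_matrices(out)
  out
}

#' @export
print.gauss_coef <- function(x, ...) {
  cat(
    "<gauss_coef> ", x$model_name, " epoch ", format(x$epoch),
    ", n_max ", x$n_max, ", ", nrow(x$coef), " coefficient rows\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.gauss_coef <- function(x, ...) {
  out <- x$coef
  out$epoch <- x$epoch
  out
}

# coefficient matrices indexed [n, m + 1], n = 1..n_max, for evaluation
coef_matrices <- function(x, which = c("g", "h", "g_dot", "h_dot",
                            "g_ddot", "h_ddot")) {
  if (!is.null(x$mats)) return(x$mats)
  out <- lapply(which, function(w) {
    mat <- matrix(0, x$n_max, x$n_max + 1)
    mat[cbind(x$coef$n, x$coef$m + 1)] <- x$coef[[w]]
    mat
  })
  names(out) <- which
  out
}

#' Propagate Gauss coefficients to a time
#'
#' Applies the secular-variation model
#' `g(t) = g + g_dot (t - t0) + g_ddot (t - t0)^2` (and the same for
#' `h`); the quadratic term contributes only when quadratic rates were
#' supplied. Returns an instantaneous set whose epoch is `t` and whose
#' rate terms are zero.
#'
#' @param x A [gauss_coefficients()] object.
#' @param t Decimal year.
#' @return A `gauss_coef` object valid at `t`.
#' @export
coefficients_at_time <- function(x, t) {
  stopifnot(inherits(x, "gauss_coef"))
  check_finite(t, "t")
  dt <- t - x$epoch
  co <- x$coef
  gauss_coefficients(
    n = co$n, m = co$m,
    g = co$g + co$g_dot * dt + co$g_ddot * dt^2,
    h = co$h + co$h_dot * dt + co$h_ddot * dt^2,
    epoch = t, model_name = x$model_name, n_max = x$n_max, a = x$a
  )
}

#' Read and write WMM-style .COF coefficient files
#'
#' The plain-text dialect has a header line `epoch model_name date`,
#' one body line `n m g h g_dot h_dot` per coefficient pair, and an
#' optional terminator line of 9s. Quadratic rates are not representable
#' in the format and default to zero on read. `write_cof()` prints with
#' enough digits that a write/read cycle reproduces every coefficient
#' bit-exactly.
#'
#' @param path File path.
#' @return `read_cof()` returns a `gauss_coef`; `write_cof()` returns
#'   `path` invisibly.
#' @export
read_cof <- function(path) {
  if (!file.exists(path)) {
    abort_circmag(paste0("No such file: ", path), "io")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) {
    abort_circmag("Coefficient file has no body rows.", "format")
  }
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  epoch <- suppressWarnings(as.numeric(header[1]))
  if (is.na(epoch)) {
    abort_circmag("Header line must start with a decimal-year epoch.",
      "format"
    )
  }
  model_name <- if (length(header) >= 2) header[2] else "UNKNOWN"
  body <- lines[-1]
  body <- body[!grepl("^9{6,}", trimws(body))] # terminator row(s)
  rows <- lapply(seq_along(body), function(i) {
    fields <- strsplit(trimws(body[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 6 || anyNA(vals)) {
      abort_circmag(
        paste0("Malformed coefficient row at line ", i + 1, "."),
        "format"
      )
    }
    if (vals[2] > vals[1]) {
      abort_circmag(
        paste0("Order m exceeds degree n at line ", i + 1, "."),
        "format"
      )
    }
    vals
  })
  tab <- do.call(rbind, rows)
  if (anyDuplicated(tab[, 1:2])) {
    dup <- which(duplicated(tab[, 1:2]))[1]
    abort_circmag(
      paste0("Duplicate (n, m) pair at line ", dup + 1, "."),
      "format"
    )
  }
  gauss_coefficients(
    n = tab[, 1], m = tab[, 2], g = tab[, 3], h = tab[, 4],
    g_dot = tab[, 5], h_dot = tab[, 6],
    epoch = epoch, model_name = model_name
  )
}

#' @rdname read_cof
#' @param x A `gauss_coef` object.
#' @export
write_cof <- function(x, path) {
  stopifnot(inherits(x, "gauss_coef"))
  num <- function(v) formatC(v, digits = 17, format = "g")
  header <- paste("   ", num(x$epoch), "           ", x$model_name)
  body <- sprintf(
    "%3d %3d %s %s %s %s",
    x$coef$n, x$coef$m,
    num(x$coef$g), num(x$coef$h), num(x$coef$g_dot), num(x$coef$h_dot)
  )
  terminator <- paste(rep("9", 48), collapse = "")
  writeLines(c(header, body, terminator), path)
  invisible(path)
}
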