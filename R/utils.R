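# Internal helpers shared across modules.

copd_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "copdflow_error"), ...)
}

# Locate a bundled data file under inst/extdata.
copd_sys_file <- function(name) {
  path <- system.file("extdata", name, package = "copdflow")
  if (!nzchar(path)) {
    copd_abort(paste0("bundled data file not found: ", name), "copd_missing_data")
  }
  path
}

# Band lookup over a table with columns lower/upper and a value column.
# `closed` = "left" means [lower, upper); "right" means (lower, upper].
# Returns the value column entry for each x; NA when no band matches.
band_lookup <- function(x, bands, value_col, closed = "left") {
  stopifnot(value_col %in% names(bands))
  out <- rep(bands[[value_col]][NA_integer_], length(x))
  for (i in seq_len(nrow(bands))) {
    cl <- if ("closed" %in% names(bands)) bands$closed[i] else closed
    hit <- if (identical(cl, "right")) {
      x > bands$lower[i] & x <= bands$upper[i]
    } else {
      x >= bands$lower[i] & x < bands$upper[i]
    }
    hit[is.na(hit)] <- FALSE
    out[hit] <- bands[[value_col]][i]
  }
  out
}

# Contiguity check for a band table: sorted by lower, each upper must equal
# the next lower; the union must cover [domain_min, domain_max).
check_band_coverage <- function(bands, domain_min, domain_max, what = "band table") {
  b <- bands[order(bands$lower), , drop = FALSE]
  if (nrow(b) == 0L) {
    copd_abort(paste0(what, " is empty"), "copd_config_error")
  }
  if (b$lower[1] > domain_min) {
    copd_abort(
      sprintf("%s has a gap below %s (first band starts at %s)",
              what, format(domain_min), format(b$lower[1])),
      "copd_config_error"
    )
  }
  if (nrow(b) > 1L) {
    for (i in seq_len(nrow(b) - 1L)) {
      if (b$upper[i] < b$lower[i + 1L]) {
        copd_abort(
          sprintf("%s has a gap between %s and %s",
                  what, format(b$upper[i]), format(b$lower[i + 1L])),
          "copd_config_error"
        )
      }
      if (b$upper[i] > b$lower[i + 1L]) {
        copd_abort(
          sprintf("%s has overlapping bands at %s", what, format(b$lower[i + 1L])),
          "copd_config_error"
        )
      }
    }
  }
  if (b$upper[nrow(b)] < domain_max) {
    copd_abort(
      sprintf("%s does not cover values up to %s", what, format(domain_max)),
      "copd_config_error"
    )
  }
  invisible(TRUE)
}

# Seed derivation: one reproducible stream per (seed, id), kept within the
# 32-bit integer range R requires.
derive_seed <- function(seed, id) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(id) * 9973) %% 2147483647)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (is.character(x)) {
    y <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    bad <- is.na(y) & !is.na(x)
    if (any(bad)) y[bad] <- as.POSIXct(x[bad], tz = "UTC")
    return(y)
  }
  if (is.numeric(x)) {
    return(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"))
  }
  as.POSIXct(x, tz = "UTC")
}

format_iso8601 <- function(x) {
  format(as_utc(x), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

parse_iso8601 <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}
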