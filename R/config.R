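#' Engine configuration
#'
#' Build the configuration object every other function in the package consumes.
#' All clinical thresholds of the redesigned diagnostic pathway live here with
#' their defaults: the opportunistic-screening age cut (strictly over 40 years),
#' the 2-year screening revalidation window, the 24-hour appointment-reminder
#' lead, the 24-hour spirometer calibration window, the 0.15 L session
#' reproducibility criterion, the 6-second minimum forced expiratory time, the
#' obstruction threshold mode (demographic lower limit of normal, with the
#' fixed 0.7 ratio as the alternative), and the referral rule (severe or very
#' severe disease, or frequent exacerbations). Clinical lookup tables (screening
#' instrument, reference equations, BODE/BODEx cut-points, severity and impact
#' bands, the differential-diagnosis knowledge base, the process model) are
#' loaded from the bundled data files unless a replacement path is given.
#'
#' @param ... Named overrides of any configuration field; see Details.
#' @param config_file Optional YAML or JSON document of overrides; explicit
#'   `...` arguments take precedence over the file.
#'
#' @details
#' Duration fields are numeric with the unit in the field name
#' (`reminder_lead_hours`, `revalidation_years`, `calibration_max_age_hours`,
#' `no_show_window_days`). Band tables are validated for full, gap-free,
#' non-overlapping coverage of their score range, and every clinical data file
#' must carry a provenance label (a non-empty `source` column).
#'
#' @return A `copd_config` list with all tunables and loaded lookup tables.
#' @examples
#' cfg <- engine_config()
#' cfg$repro_threshold_l
#' engine_config(obstruction_mode = "fixed")$obstruction_mode
#' @export
engine_config <- function(..., config_file = NULL) {
  overrides <- list(...)
  if (!is.null(config_file)) {
    doc <- read_config_document(config_file)
    overrides <- modifyList(doc, overrides)
  }
  validate_config(overrides)
}

config_defaults <- function() {
  list(
    age_cut = 40,
    revalidation_years = 2,
    reminder_lead_hours = 24,
    calibration_max_age_hours = 24,
    repro_threshold_l = 0.15,
    min_fet_s = 6,
    obstruction_mode = "lln",
    fixed_ratio_cut = 0.7,
    frequent_exacerbation_threshold = 2,
    hospitalization_referral_threshold = 1,
    index_precedence = "bode",
    severity_driver = "index",
    no_show_window_days = 7,
    max_session_retries = 3,
    instrument_path = NULL,
    equations_path = NULL,
    bode_cutpoints_path = NULL,
    bodex_cutpoints_path = NULL,
    severity_bands_path = NULL,
    impact_bands_path = NULL,
    kb_path = NULL,
    vocabulary_path = NULL,
    process_model_path = NULL
  )
}

read_config_document <- function(path) {
  if (!file.exists(path)) {
    copd_abort(paste0("config file not found: ", path), "copd_config_error")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path) %||% list()
  }
}

#' Validate a configuration document
#'
#' Fill defaults into a (possibly empty) list of overrides, load the referenced
#' clinical data files, and check the structural invariants: positive
#' thresholds, gap-free and non-overlapping band tables covering the full score
#' range of each index, and a provenance label on every clinical data file.
#'
#' @param document A named list of overrides (or an empty list for pure
#'   defaults).
#' @return A validated `copd_config` object.
#' @examples
#' cfg <- validate_config(list())
#' cfg$age_cut
#' @export
validate_config <- function(document = list()) {
  if (!is.list(document)) {
    copd_abort("config document must be a named list", "copd_config_error")
  }
  unknown <- setdiff(names(document), names(config_defaults()))
  if (length(unknown) > 0L) {
    copd_abort(
      paste0("unknown config field(s): ", paste(unknown, collapse = ", ")),
      "copd_config_error"
    )
  }
  cfg <- modifyList(config_defaults(), document, keep.null = TRUE)

  positive_fields <- c(
    "revalidation_years", "reminder_lead_hours", "calibration_max_age_hours",
    "repro_threshold_l", "min_fet_s", "fixed_ratio_cut",
    "no_show_window_days"
  )
  for (f in positive_fields) {
    if (!is_scalar_number(cfg[[f]]) || cfg[[f]] <= 0) {
      copd_abort(paste0("config field ", f, " must be a positive number"),
                 "copd_config_error")
    }
  }
  if (!is_scalar_number(cfg$age_cut) || cfg$age_cut < 0) {
    copd_abort("age_cut must be a non-negative number", "copd_config_error")
  }
  if (!cfg$obstruction_mode %in% c("lln", "fixed")) {
    copd_abort("obstruction_mode must be 'lln' or 'fixed'", "copd_config_error")
  }
  if (!cfg$index_precedence %in% c("bode", "bodex")) {
    copd_abort("index_precedence must be 'bode' or 'bodex'", "copd_config_error")
  }
  if (!cfg$severity_driver %in% c("index", "fev1_pct")) {
    copd_abort("severity_driver must be 'index' or 'fev1_pct'", "copd_config_error")
  }

  cfg$instrument <- load_instrument(cfg$instrument_path %||%
                                      copd_sys_file("screening_instrument.yaml"))
  cfg$equations <- load_reference_equations(cfg$equations_path %||%
                                              copd_sys_file("reference_equations_synthetic.csv"))
  cfg$bode_cutpoints <- load_cutpoints(cfg$bode_cutpoints_path %||%
                                         copd_sys_file("bode_cutpoints.csv"),
                                       components = c("bmi", "fev1_pct", "mmrc", "six_mwd"))
  cfg$bodex_cutpoints <- load_cutpoints(cfg$bodex_cutpoints_path %||%
                                          copd_sys_file("bodex_cutpoints.csv"),
                                        components = c("bmi", "fev1_pct", "mmrc", "exacerbations"))
  cfg$severity_bands <- load_severity_bands(cfg$severity_bands_path %||%
                                              copd_sys_file("severity_bands.csv"))
  cfg$impact_bands <- load_impact_bands(cfg$impact_bands_path %||%
                                          copd_sys_file("impact_bands.csv"))
  cfg$kb <- load_knowledge_base(cfg$kb_path %||% copd_sys_file("differential_kb.csv"),
                                vocabulary_path = cfg$vocabulary_path)
  cfg$process_model <- load_process_model(cfg$process_model_path %||%
                                            copd_sys_file("process_model.yaml"))

  structure(cfg, class = "copd_config")
}

require_provenance <- function(tbl, path) {
  if (!"source" %in% names(tbl) || any(!nzchar(tbl$source)) || any(is.na(tbl$source))) {
    copd_abort(
      paste0("clinical data file lacks a provenance label ('source' column): ", path),
      "copd_config_error"
    )
  }
  invisible(tbl)
}

load_cutpoints <- function(path, components) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("source", "component", "points", "lower", "upper", "closed")
  if (!all(needed %in% names(tbl))) {
    copd_abort(paste0("cut-point file must have columns ",
                      paste(needed, collapse = ", "), ": ", path),
               "copd_config_error")
  }
  require_provenance(tbl, path)
  missing <- setdiff(components, unique(tbl$component))
  if (length(missing) > 0L) {
    copd_abort(paste0("cut-point file missing component(s): ",
                      paste(missing, collapse = ", ")),
               "copd_config_error")
  }
  as_tibble(tbl)
}

load_severity_bands <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_provenance(tbl, path)
  domains <- list(bode = c(0, 11), bodex = c(0, 10), fev1_pct = c(0, Inf))
  for (idx in intersect(names(domains), unique(tbl$index))) {
    b <- tbl[tbl$index == idx, , drop = FALSE]
    check_band_coverage(b, domains[[idx]][1], domains[[idx]][2],
                        what = paste0("severity band table (", idx, ")"))
  }
  for (idx in c("bode", "bodex")) {
    if (!idx %in% tbl$index) {
      copd_abort(paste0("severity band table lacks bands for index ", idx),
                 "copd_config_error")
    }
  }
  as_tibble(tbl)
}

load_impact_bands <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_provenance(tbl, path)
  check_band_coverage(tbl, 0, 41, what = "impact band table (CAT)")
  as_tibble(tbl)
}

#' @export
print.copd_config <- function(x, ...) {
  cat("<copd_config>\n")
  cat("  obstruction mode:", x$obstruction_mode,
      if (identical(x$obstruction_mode, "fixed"))
        paste0("(ratio < ", x$fixed_ratio_cut, ")") else "(ratio < LLN)", "\n")
  cat("  screening: age >", x$age_cut, "; revalidation",
      x$revalidation_years, "y\n")
  cat("  spirometry: reproducibility Δ ≤", x$repro_threshold_l,
      "L; calibration ≤", x$calibration_max_age_hours, "h; FET ≥",
      x$min_fet_s, "s\n")
  cat("  staging: precedence", x$index_precedence, "; referral on severe+ or ≥",
      x$frequent_exacerbation_threshold, "exacerbations/yr\n")
  invisible(x)
}

#' Serialize a configuration to YAML
#'
#' Writes the tunable scalar fields (not the loaded tables) so that the
#' document round-trips through [validate_config()] unchanged.
#'
#' @param config A `copd_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "copd_config"))
  fields <- config_defaults()
  out <- config[names(fields)]
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}
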