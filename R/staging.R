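# Per-component point lookup against a cut-point table (vectorized).
component_points <- function(x, component, cutpoints) {
  rows <- cutpoints[cutpoints$component == component, , drop = FALSE]
  if (nrow(rows) == 0L) {
    copd_abort(paste0("cut-point table has no component '", component, "'"),
               "copd_staging_error")
  }
  pts <- band_lookup(x, rows, "points")
  if (any(is.na(pts) & !is.na(x))) {
    copd_abort(paste0("value outside the ", component, " cut-point bands"),
               "copd_staging_error")
  }
  pts
}

require_fields <- function(x, fields, context) {
  for (f in fields) {
    v <- x[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v)) {
      if (identical(f, "six_mwd")) {
        copd_abort("6-minute-walk distance unavailable", "copd_bode_unavailable")
      }
      copd_abort(paste0(context, " requires field '", f, "'"),
                 "copd_missing_field")
    }
  }
  invisible(TRUE)
}

#' BODE index
#'
#' Composite severity index summing four component scores: body-mass index
#' (0–1), airflow obstruction as FEV1 percent predicted (0–3), dyspnea as the
#' mMRC grade (0–3) and exercise capacity as the 6-minute-walk distance
#' (0–3); range 0–10, higher is worse. Cut-points come from the bundled
#' transcription of the published index table and are replaceable via config.
#'
#' @param assessment Named list or one-row tibble with `bmi` (kg/m2),
#'   `fev1_pct` (%), `mmrc` (0–4), `six_mwd` (meters).
#' @param cutpoints Cut-point table (default: bundled BODE table).
#' @return A list: `score` (0–10) and `points` (named per-component vector).
#' @examples
#' bode_score(list(bmi = 20, fev1_pct = 65, mmrc = 2, six_mwd = 400))$score
#' @export
bode_score <- function(assessment,
                       cutpoints = engine_config()$bode_cutpoints) {
  require_fields(assessment, c("bmi", "fev1_pct", "mmrc", "six_mwd"), "BODE")
  validate_assessment_ranges(assessment)
  pts <- c(
    bmi = component_points(assessment[["bmi"]], "bmi", cutpoints),
    fev1_pct = component_points(assessment[["fev1_pct"]], "fev1_pct", cutpoints),
    mmrc = component_points(assessment[["mmrc"]], "mmrc", cutpoints),
    six_mwd = component_points(assessment[["six_mwd"]], "six_mwd", cutpoints)
  )
  list(score = sum(pts), points = pts)
}

#' BODEx index
#'
#' BODE variant replacing the exercise component with the past-year
#' exacerbation count (0–2); range 0–9, higher is worse.
#'
#' @param assessment Named list or one-row tibble with `bmi`, `fev1_pct`,
#'   `mmrc`, `exacerbations`.
#' @param cutpoints Cut-point table (default: bundled BODEx table).
#' @return A list: `score` (0–9) and `points` (named per-component vector).
#' @examples
#' bodex_score(list(bmi = 23, fev1_pct = 40, mmrc = 3, exacerbations = 2))$score
#' @export
bodex_score <- function(assessment,
                        cutpoints = engine_config()$bodex_cutpoints) {
  require_fields(assessment, c("bmi", "fev1_pct", "mmrc", "exacerbations"), "BODEx")
  validate_assessment_ranges(assessment)
  pts <- c(
    bmi = component_points(assessment[["bmi"]], "bmi", cutpoints),
    fev1_pct = component_points(assessment[["fev1_pct"]], "fev1_pct", cutpoints),
    mmrc = component_points(assessment[["mmrc"]], "mmrc", cutpoints),
    exacerbations = component_points(assessment[["exacerbations"]],
                                     "exacerbations", cutpoints)
  )
  list(score = sum(pts), points = pts)
}

validate_assessment_ranges <- function(a) {
  if (!is.null(a[["mmrc"]]) && length(a[["mmrc"]]) == 1L && !is.na(a[["mmrc"]])) {
    if (!a[["mmrc"]] %in% 0:4) {
      copd_abort("mMRC grade must be an integer in 0..4", "copd_staging_error")
    }
  }
  if (!is.null(a[["fev1_pct"]]) && length(a[["fev1_pct"]]) == 1L &&
      !is.na(a[["fev1_pct"]]) && a[["fev1_pct"]] <= 0) {
    copd_abort("FEV1 percent predicted must be positive", "copd_staging_error")
  }
  if (!is.null(a[["exacerbations"]]) && length(a[["exacerbations"]]) == 1L &&
      !is.na(a[["exacerbations"]]) && a[["exacerbations"]] < 0) {
    copd_abort("exacerbation count must be non-negative", "copd_staging_error")
  }
  invisible(TRUE)
}

#' Severity level from an index score
#'
#' Maps a BODE/BODEx score (or, as the alternative driver, FEV1 percent
#' predicted) to the four severity levels — mild, moderate, severe, very
#' severe — via the configured band table. The mapping is nondecreasing in the
#' driving score for BODE/BODEx (and in disease severity for the FEV1 driver).
#'
#' @param score Index score (vectorized).
#' @param index `"bode"`, `"bodex"`, or `"fev1_pct"`.
#' @param bands Severity band table.
#' @return Character vector of levels, ordered factor levels
#'   mild < moderate < severe < very_severe.
#' @examples
#' severity_level(5, "bode")
#' @export
severity_level <- function(score, index = c("bode", "bodex", "fev1_pct"),
                           bands = engine_config()$severity_bands) {
  index <- match.arg(index)
  b <- bands[bands$index == index, , drop = FALSE]
  rng <- switch(index, bode = c(0, 10), bodex = c(0, 9), fev1_pct = c(0, Inf))
  if (any(score < rng[1] | score > rng[2], na.rm = TRUE)) {
    copd_abort(paste0(index, " score out of range [", rng[1], ", ", rng[2], "]"),
               "copd_staging_error")
  }
  lvl <- band_lookup(score, b, "level")
  factor(lvl, levels = c("mild", "moderate", "severe", "very_severe"),
         ordered = TRUE)
}

#' Impact level from the CAT score
#'
#' Maps the COPD Assessment Test total (0–40) to the four quality-of-life
#' impact levels — low, moderate, high, very high (defaults: <10 / 10–20 /
#' 21–30 / >30).
#'
#' @param cat_score CAT total (vectorized).
#' @param bands Impact band table.
#' @return Ordered factor low < moderate < high < very_high.
#' @examples
#' impact_level(15)
#' @export
impact_level <- function(cat_score, bands = engine_config()$impact_bands) {
  if (any(cat_score < 0 | cat_score > 40, na.rm = TRUE)) {
    copd_abort("CAT score out of range [0, 40]", "copd_staging_error")
  }
  lvl <- band_lookup(cat_score, bands, "level")
  factor(lvl, levels = c("low", "moderate", "high", "very_high"),
         ordered = TRUE)
}

#' Specialist referral decision
#'
#' Refer when severity is severe or very severe, or when exacerbations are
#' frequent (at or above the configured count per year, default 2, or at least
#' one hospitalization). A flagged referral must carry a complete structured
#' report (scores, spirometry summary, exacerbation history); an incomplete
#' report is rejected with an error naming the missing field.
#'
#' @param severity A severity level (from [severity_level()]).
#' @param assessment Assessment with `exacerbations` and optionally
#'   `hospitalizations`.
#' @param config Engine configuration.
#' @param report Named list of report fields; mandatory when the referral is
#'   flagged: `scores`, `spirometry_summary`, `exacerbation_history`.
#'   Optional: `comorbidity_notes`.
#' @return A list: `refer` (logical), `reasons` (character), `report` (the
#'   validated report, or `NULL` when not referred).
#' @examples
#' referral_decision("severe", list(exacerbations = 0),
#'                   report = list(scores = list(bodex = 5),
#'                                 spirometry_summary = "ratio 0.58 < LLN 0.65",
#'                                 exacerbation_history = "none"))$refer
#' @export
referral_decision <- function(severity, assessment,
                              config = engine_config(), report = NULL) {
  sev <- as.character(severity)
  exac <- assessment[["exacerbations"]] %||% 0
  hosp <- assessment[["hospitalizations"]] %||% 0
  reasons <- c(
    if (sev %in% c("severe", "very_severe")) "severity",
    if (exac >= config$frequent_exacerbation_threshold) "frequent_exacerbations",
    if (hosp >= config$hospitalization_referral_threshold) "hospitalizations"
  )
  refer <- length(reasons) > 0L
  if (refer) {
    mandatory <- c("scores", "spirometry_summary", "exacerbation_history")
    for (f in mandatory) {
      v <- report[[f]]
      if (is.null(v) || (length(v) == 1L && (is.na(v) || identical(v, "")))) {
        copd_abort(paste0("referral report incomplete: missing field '", f, "'"),
                   "copd_report_error")
      }
    }
  }
  list(refer = refer, reasons = reasons %||% character(),
       report = if (refer) report else NULL)
}

#' Stage a table of assessments
#'
#' Vectorised staging for a cohort: per-component BODE/BODEx points, index
#' scores, the driving index per the configured precedence (BODE when the
#' 6-minute-walk distance is available, BODEx otherwise, unless the FEV1
#' driver is configured), severity and impact levels, and the referral flag.
#'
#' @param assessments Tibble with columns `bmi`, `fev1_pct`, `mmrc`,
#'   `exacerbations`, and optionally `six_mwd`, `hospitalizations`,
#'   `cat_score`.
#' @param config Engine configuration.
#' @return The input tibble with `bodex`, `bode` (NA without 6MWD),
#'   `driving_index`, `severity`, `impact` (NA without CAT), `refer` columns.
#' @examples
#' stage_patients(tibble::tibble(bmi = 23, fev1_pct = 40, mmrc = 3,
#'                               exacerbations = 2, cat_score = 15))
#' @export
stage_patients <- function(assessments, config = engine_config()) {
  df <- as_tibble(assessments)
  if (!"six_mwd" %in% names(df)) df$six_mwd <- NA_real_
  if (!"hospitalizations" %in% names(df)) df$hospitalizations <- 0
  if (!"cat_score" %in% names(df)) df$cat_score <- NA_real_

  cpx <- config$bodex_cutpoints
  cpd <- config$bode_cutpoints
  df$bodex <- component_points(df$bmi, "bmi", cpx) +
    component_points(df$fev1_pct, "fev1_pct", cpx) +
    component_points(df$mmrc, "mmrc", cpx) +
    component_points(df$exacerbations, "exacerbations", cpx)

  has_walk <- !is.na(df$six_mwd)
  df$bode <- NA_real_
  if (any(has_walk)) {
    df$bode[has_walk] <- component_points(df$bmi[has_walk], "bmi", cpd) +
      component_points(df$fev1_pct[has_walk], "fev1_pct", cpd) +
      component_points(df$mmrc[has_walk], "mmrc", cpd) +
      component_points(df$six_mwd[has_walk], "six_mwd", cpd)
  }

  if (identical(config$severity_driver, "fev1_pct")) {
    df$driving_index <- "fev1_pct"
    df$severity <- severity_level(df$fev1_pct, "fev1_pct", config$severity_bands)
  } else {
    use_bode <- has_walk & identical(config$index_precedence, "bode")
    df$driving_index <- ifelse(use_bode, "bode", "bodex")
    sev <- character(nrow(df))
    if (any(use_bode)) {
      sev[use_bode] <- as.character(
        severity_level(df$bode[use_bode], "bode", config$severity_bands))
    }
    if (any(!use_bode)) {
      sev[!use_bode] <- as.character(
        severity_level(df$bodex[!use_bode], "bodex", config$severity_bands))
    }
    df$severity <- factor(sev, levels = c("mild", "moderate", "severe",
                                          "very_severe"), ordered = TRUE)
  }

  df$impact <- impact_level(df$cat_score, config$impact_bands)
  df$refer <- df$severity %in% c("severe", "very_severe") |
    df$exacerbations >= config$frequent_exacerbation_threshold |
    df$hospitalizations >= config$hospitalization_referral_threshold
  df
}
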