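#' Spirometer calibration check
#'
#' The device passes when the last calibration is no older than the configured
#' window (default 24 h, inclusive at the boundary).
#'
#' @param last_calibration Timestamp of the last calibration.
#' @param clock Current timestamp; must not precede `last_calibration`.
#' @param max_age_hours Maximum calibration age in hours.
#' @return `TRUE`/`FALSE`.
#' @examples
#' check_calibration("2024-03-01T06:00:00Z", "2024-03-01T08:00:00Z")
#' @export
check_calibration <- function(last_calibration, clock, max_age_hours = 24) {
  last <- as_utc(last_calibration)
  now <- as_utc(clock)
  if (last > now) {
    copd_abort("last calibration is in the future", "copd_data_error")
  }
  as.numeric(difftime(now, last, units = "hours")) <= max_age_hours
}

#' Flag attempt quality
#'
#' Attempt acceptability follows the failure patterns a nurse checks on the
#' volume–flow tracing: slow start, early termination, glottis closure and
#' variable effort. Curve-shape detection is operator-assisted — those flags
#' are inputs — except `early_termination`, which is computed from the forced
#' expiratory time when available (FET below the configured minimum, default
#' 6 s). An attempt with any flag set is excluded from the acceptable subset.
#'
#' @param attempts Tibble of attempts with numeric `fvc`, `fev1`, optional
#'   `fet`, and optional logical flag columns `slow_start`, `early_termination`,
#'   `glottis_closure`, `variable_effort` (missing columns default to FALSE).
#' @param min_fet_s Minimum forced expiratory time (seconds).
#' @return The input tibble with all four flag columns filled and an
#'   `acceptable` column.
#' @examples
#' flag_attempt_quality(tibble::tibble(fvc = 3.2, fev1 = 2.1, fet = 4))
#' @export
flag_attempt_quality <- function(attempts, min_fet_s = 6) {
  flags <- c("slow_start", "early_termination", "glottis_closure", "variable_effort")
  for (f in flags) {
    if (!f %in% names(attempts)) attempts[[f]] <- FALSE
    attempts[[f]][is.na(attempts[[f]])] <- FALSE
  }
  if ("fet" %in% names(attempts)) {
    short <- !is.na(attempts$fet) & attempts$fet < min_fet_s
    attempts$early_termination <- attempts$early_termination | short
  }
  validate_attempt_values(attempts)
  attempts$acceptable <- !(attempts$slow_start | attempts$early_termination |
                             attempts$glottis_closure | attempts$variable_effort)
  attempts
}

validate_attempt_values <- function(attempts) {
  if (any(is.na(attempts$fvc)) || any(is.na(attempts$fev1))) {
    copd_abort("attempt has missing FVC or FEV1", "copd_data_error")
  }
  if (any(attempts$fev1 <= 0) || any(attempts$fev1 > attempts$fvc)) {
    copd_abort("attempt violates 0 < FEV1 <= FVC", "copd_data_error")
  }
  if (any(attempts$fvc <= 0.2) || any(attempts$fvc >= 10)) {
    copd_abort("attempt FVC outside the (0.2, 10) L plausibility band",
               "copd_data_error")
  }
  invisible(attempts)
}

#' Session reproducibility criterion
#'
#' With at least three acceptable attempts, the session is reproducible when
#' the difference between the two best FVC values and between the two best
#' FEV1 values are each at most the threshold (default 0.15 L, inclusive).
#' With more than three acceptable attempts the two-best rule is applied over
#' all of them (more attempts can only help).
#'
#' @param attempts Tibble of acceptable attempts with `fvc` and `fev1`
#'   (liters). Pass the acceptable subset; rows are not re-filtered.
#' @param threshold_l Reproducibility threshold in liters.
#' @return A list: `reproducible` (logical), `delta_fvc`, `delta_fev1`
#'   (liters; NA when fewer than 2 attempts), `reason` (`"ok"`,
#'   `"insufficient_attempts"`, `"delta_fvc"`, `"delta_fev1"` or both).
#' @examples
#' check_reproducibility(tibble::tibble(fvc = c(3.30, 3.20, 3.10),
#'                                      fev1 = c(2.20, 2.10, 2.05)))
#' @export
check_reproducibility <- function(attempts, threshold_l = 0.15) {
  n <- nrow(attempts)
  if (n < 3L) {
    return(list(reproducible = FALSE,
                delta_fvc = if (n >= 2L) diff(sort(attempts$fvc, decreasing = TRUE)[2:1]) else NA_real_,
                delta_fev1 = if (n >= 2L) diff(sort(attempts$fev1, decreasing = TRUE)[2:1]) else NA_real_,
                reason = "insufficient_attempts"))
  }
  fvc_sorted <- sort(attempts$fvc, decreasing = TRUE)
  fev1_sorted <- sort(attempts$fev1, decreasing = TRUE)
  delta_fvc <- fvc_sorted[1] - fvc_sorted[2]
  delta_fev1 <- fev1_sorted[1] - fev1_sorted[2]
  # inclusive boundary: a delta of exactly the threshold passes; 1e-9 L absorbs
  # binary representation error in values recorded on a 0.01 L lattice
  eps <- 1e-9
  fails <- c(if (delta_fvc > threshold_l + eps) "delta_fvc",
             if (delta_fev1 > threshold_l + eps) "delta_fev1")
  list(
    reproducible = length(fails) == 0L,
    delta_fvc = delta_fvc,
    delta_fev1 = delta_fev1,
    reason = if (length(fails) == 0L) "ok" else paste(fails, collapse = "+")
  )
}

#' Best values of a session
#'
#' Best FVC and best FEV1 are per-parameter maxima over the acceptable
#' attempts and may come from different attempts.
#'
#' @param attempts Tibble of acceptable attempts with `fvc`, `fev1`.
#' @return A list with `best_fvc` and `best_fev1` (liters).
#' @export
select_best <- function(attempts) {
  if (nrow(attempts) == 0L) {
    copd_abort("no acceptable attempts", "copd_no_acceptable_attempts")
  }
  list(best_fvc = max(attempts$fvc), best_fev1 = max(attempts$fev1))
}

#' Classify airflow obstruction
#'
#' Fixed mode calls obstruction when FEV1/FVC is strictly below the fixed cut
#' (default 0.7); LLN mode compares against the patient's demographic lower
#' limit of normal instead. The ratio is carried at full precision; no
#' rounding is applied before the comparison.
#'
#' @param best_fev1,best_fvc Best session values (liters).
#' @param mode `"fixed"` or `"lln"`.
#' @param lln LLN of the FEV1/FVC ratio (required in `"lln"` mode).
#' @param fixed_cut Fixed threshold used in `"fixed"` mode.
#' @return A list: `obstructed`, `ratio`, `threshold`, `mode`.
#' @examples
#' classify_obstruction(2.0, 3.0, mode = "fixed")
#' @export
classify_obstruction <- function(best_fev1, best_fvc, mode = c("lln", "fixed"),
                                 lln = NULL, fixed_cut = 0.7) {
  mode <- match.arg(mode)
  ratio <- best_fev1 / best_fvc
  threshold <- if (identical(mode, "fixed")) {
    fixed_cut
  } else {
    if (!is_scalar_number(lln)) {
      copd_abort("lln mode requires an LLN value", "copd_config_error")
    }
    lln
  }
  list(obstructed = ratio < threshold, ratio = ratio,
       threshold = threshold, mode = mode)
}

#' Validate and interpret a spirometry session
#'
#' Full session pipeline: calibration check, attempt quality flags, the
#' acceptable subset, the two-best reproducibility criterion, best-value
#' selection, and — when the session is valid (calibrated and reproducible) —
#' the obstruction call in the configured threshold mode. The obstruction flag
#' is undefined (NA) for invalid sessions.
#'
#' @param attempts Tibble of attempts (`fvc`, `fev1`, optional `fet` and
#'   operator flag columns).
#' @param patient Patient demographics (`age`, `sex`, `height`, optional
#'   `group`) — needed for LLN mode.
#' @param last_calibration Timestamp of the device's last calibration.
#' @param clock Session timestamp.
#' @param config Engine configuration.
#' @return A `copd_session` list: `calibrated`, `attempts` (flagged tibble),
#'   `n_acceptable`, `reproducible`, `delta_fvc`, `delta_fev1`, `valid`,
#'   `best_fvc`, `best_fev1`, `ratio`, `lln_ratio`, `threshold`, `mode`,
#'   `obstructed`, `reason`.
#' @examples
#' att <- tibble::tibble(fvc = c(3.3, 3.2, 3.25), fev1 = c(2.1, 2.0, 2.05))
#' s <- assess_session(att, list(age = 60, sex = "male", height = 175),
#'                     "2024-03-01T07:00:00Z", "2024-03-01T09:00:00Z")
#' s$valid
#' @export
assess_session <- function(attempts, patient = NULL,
                           last_calibration, clock,
                           config = engine_config()) {
  calibrated <- check_calibration(last_calibration, clock,
                                  config$calibration_max_age_hours)
  attempts <- flag_attempt_quality(attempts, config$min_fet_s)
  acc <- attempts[attempts$acceptable, , drop = FALSE]
  repro <- check_reproducibility(acc, config$repro_threshold_l)
  valid <- calibrated && repro$reproducible

  best_fvc <- best_fev1 <- ratio <- NA_real_
  if (nrow(acc) > 0L) {
    best <- select_best(acc)
    best_fvc <- best$best_fvc
    best_fev1 <- best$best_fev1
    ratio <- best_fev1 / best_fvc
  }

  lln_ratio <- NA_real_
  threshold <- NA_real_
  obstructed <- NA
  if (valid) {
    if (identical(config$obstruction_mode, "lln")) {
      if (is.null(patient)) {
        copd_abort("lln mode requires patient demographics", "copd_config_error")
      }
      lln_ratio <- compute_lln(patient, config$equations)$lln_ratio
    }
    call <- classify_obstruction(best_fev1, best_fvc,
                                 mode = config$obstruction_mode,
                                 lln = if (identical(config$obstruction_mode, "lln"))
                                   lln_ratio else NULL,
                                 fixed_cut = config$fixed_ratio_cut)
    obstructed <- call$obstructed
    threshold <- call$threshold
  }

  reason <- if (!calibrated) "uncalibrated"
  else if (!repro$reproducible) repro$reason
  else "ok"

  structure(
    list(
      calibrated = calibrated,
      attempts = attempts,
      n_acceptable = nrow(acc),
      reproducible = repro$reproducible,
      delta_fvc = repro$delta_fvc,
      delta_fev1 = repro$delta_fev1,
      valid = valid,
      best_fvc = best_fvc,
      best_fev1 = best_fev1,
      ratio = ratio,
      lln_ratio = lln_ratio,
      threshold = threshold,
      mode = config$obstruction_mode,
      obstructed = obstructed,
      reason = reason
    ),
    class = "copd_session"
  )
}

#' @export
print.copd_session <- function(x, ...) {
  cat("<spirometry session>",
      if (x$valid) "valid" else paste0("invalid (", x$reason, ")"), "\n")
  if (!is.na(x$best_fvc)) {
    cat(sprintf("  best FVC %.2f L, best FEV1 %.2f L, ratio %.3f\n",
                x$best_fvc, x$best_fev1, x$ratio))
  }
  if (!is.na(x$obstructed)) {
    cat(sprintf("  obstruction: %s (%s mode, threshold %.3f)\n",
                if (x$obstructed) "YES" else "no", x$mode, x$threshold))
  }
  invisible(x)
}
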