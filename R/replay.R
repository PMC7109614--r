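#' Compare fixed-0.7 and LLN obstruction calls on a cohort
#'
#' Classifies every patient's measured best-value ratio under both threshold
#' modes. By construction the two modes can disagree only for ratios strictly
#' between the two thresholds; for elderly patients whose LLN is below 0.7 the
#' fixed cut calls at least as many obstructions — the overdiagnosis direction
#' that motivates the LLN.
#'
#' @param cohort A `copd_cohort`.
#' @param config Engine configuration.
#' @return A tibble per patient: `patient_id`, `ratio`, `lln_ratio`,
#'   `fixed_call`, `lln_call`, `true_obstructed`.
#' @export
compare_obstruction_modes <- function(cohort, config = engine_config()) {
  att <- flag_attempt_quality(cohort$sessions, config$min_fet_s)
  best <- att |>
    group_by(.data$patient_id) |>
    summarise(
      best_fvc = if (any(.data$acceptable)) max(.data$fvc[.data$acceptable])
      else max(.data$fvc),
      best_fev1 = if (any(.data$acceptable)) max(.data$fev1[.data$acceptable])
      else max(.data$fev1),
      .groups = "drop"
    ) |>
    mutate(ratio = .data$best_fev1 / .data$best_fvc)
  best |>
    left_join(select(cohort$labels, "patient_id", "lln_ratio", "true_obstructed"),
              by = "patient_id") |>
    mutate(fixed_call = .data$ratio < config$fixed_ratio_cut,
           lln_call = .data$ratio < .data$lln_ratio) |>
    select("patient_id", "ratio", "lln_ratio", "fixed_call", "lln_call",
           "true_obstructed")
}

# Assess a patient's spirometry with retries; returns the final call facts.
run_spirometry_rounds <- function(cohort, patient_index, clock, config) {
  demo <- as.list(cohort$patients[patient_index, ])
  max_rounds <- config$max_session_retries + 1L
  first_valid <- NA
  round <- 1L
  repeat {
    attempts <- if (round == 1L) {
      cohort$sessions[cohort$sessions$patient_id == demo$patient_id, ]
    } else {
      regenerate_session(cohort, patient_index, round)
    }
    sess <- assess_session(attempts, demo,
                           last_calibration = clock - 2 * 3600,
                           clock = clock, config = config)
    if (round == 1L) first_valid <- sess$valid
    if (sess$valid || round >= max_rounds) break
    round <- round + 1L
  }
  forced <- !sess$valid
  best_fvc <- sess$best_fvc
  best_fev1 <- sess$best_fev1
  if (is.na(best_fvc)) {
    # No acceptable attempts in the final session: classify from all attempts.
    best_fvc <- max(attempts$fvc)
    best_fev1 <- max(attempts$fev1)
  }
  obstructed <- if (!is.na(sess$obstructed)) sess$obstructed else {
    lln <- if (identical(config$obstruction_mode, "lln")) {
      compute_lln(demo, config$equations)$lln_ratio
    } else NULL
    classify_obstruction(best_fev1, best_fvc, mode = config$obstruction_mode,
                         lln = lln, fixed_cut = config$fixed_ratio_cut)$obstructed
  }
  list(valid = sess$valid, first_valid = first_valid, forced = forced,
       rounds = round, best_fvc = best_fvc, best_fev1 = best_fev1,
       obstructed = obstructed)
}

#' Replay a synthetic cohort through the full diagnostic process
#'
#' Runs every patient's complete cycle — appointment request, nightly
#' eligibility check, screening, reminder, consultation (or no-show),
#' spirometry with validation and retries, differential-diagnosis step,
#' severity staging and the referral decision — as process instances on the
#' bundled state machine, and scores the engine's obstruction calls against
#' the cohort's ground truth.
#'
#' @param cohort A `copd_cohort`.
#' @param config Engine configuration.
#' @return A `copd_replay` object: `results` (per-patient tibble),
#'   `confusion` (2×2 matrix of engine call vs ground truth, no-shows
#'   excluded), `metrics` (list), `instances` (the process instances),
#'   `task_durations` (from [task_duration_report()]).
#' @examples
#' rep <- end_to_end_replay(generate_cohort(cohort_spec(n = 10, seed = 1)))
#' rep$metrics$sensitivity
#' @export
end_to_end_replay <- function(cohort, config = engine_config()) {
  model <- config$process_model
  instrument <- config$instrument
  n <- nrow(cohort$patients)

  # Screening calls and clinical suspicion, precomputed per patient.
  screened <- logical(n)
  screen_positive <- rep(NA, n)
  suspected <- logical(n)
  for (i in seq_len(n)) {
    appt <- cohort$appointments[i, ]
    elig <- is_eligible_for_screening(appt$age, appt$request_time,
                                      NULL, config = config)
    screened[i] <- elig$eligible
    if (elig$eligible) {
      ans <- as.list(cohort$screening[i, instrument$items$key])
      screen_positive[i] <- score_screening(ans, instrument)$positive
    }
    ki <- key_indicator_suspicion(as.list(cohort$patients[i, ]),
                                  age_cut = config$age_cut)
    suspected[i] <- isTRUE(screen_positive[i]) || ki$suspicion
  }

  # Spirometry (only for patients who show up and are suspected).
  spiro <- vector("list", n)
  shows <- !cohort$appointments$no_show
  for (i in seq_len(n)) {
    if (shows[i] && suspected[i]) {
      spiro[[i]] <- run_spirometry_rounds(
        cohort, i, cohort$appointments$appointment_time[i] + 1800, config)
    }
  }

  # Vectorised staging for patients with an obstruction call.
  call <- map_lgl(spiro, function(s) isTRUE(s$obstructed))
  staged_idx <- which(call)
  staging <- NULL
  if (length(staged_idx) > 0L) {
    staging <- cohort$assessments[staged_idx, ] |>
      mutate(fev1_pct = 100 * map_dbl(spiro[staged_idx], "best_fev1") /
               cohort$labels$pred_fev1[staged_idx]) |>
      stage_patients(config = config)
    # Exercise the report-completeness contract for every flagged referral.
    for (j in which(staging$refer)) {
      a <- as.list(staging[j, ])
      referral_decision(
        a$severity, a, config = config,
        report = list(
          scores = list(bodex = a$bodex, bode = a$bode),
          spirometry_summary = sprintf(
            "ratio %.3f (%s mode)",
            spiro[[staged_idx[j]]]$best_fev1 / spiro[[staged_idx[j]]]$best_fvc,
            config$obstruction_mode),
          exacerbation_history = sprintf("%d exacerbations, %d hospitalizations",
                                         a$exacerbations, a$hospitalizations)
        )
      )
    }
  }

  # Drive the process instances.
  instances <- vector("list", n)
  terminal <- character(n)
  t_diag <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    appt <- cohort$appointments[i, ]
    t <- as_utc(appt$request_time)
    inst <- process_start(model, appt$patient_id, t)
    sweep_t <- as_utc(trunc(t, "days")) + 23 * 3600
    inst <- advance(inst, "eligibility_checked", sweep_t,
                    payload = list(eligible = screened[i]), model = model)
    if (screened[i]) {
      inst <- advance(inst, "screening_done", sweep_t + 2 * 3600,
                      payload = list(screening_positive = isTRUE(screen_positive[i])),
                      model = model)
      if (identical(inst$state, "suspicion_recorded")) {
        inst <- advance(inst, "suspicion_noted", sweep_t + 2 * 3600 + 60,
                        model = model)
      }
    }
    if (!shows[i]) {
      inst <- advance(inst, "no_show_timeout",
                      as_utc(appt$appointment_time) +
                        config$no_show_window_days * 86400,
                      model = model)
    } else {
      ct <- as_utc(appt$appointment_time)
      inst <- advance(inst, "patient_arrived", ct, model = model)
      inst <- advance(inst, "evaluation_done", ct + 900, model = model)
      inst <- advance(inst, "suspicion_assessed", ct + 1200,
                      payload = list(copd_suspected = suspected[i]), model = model)
      if (suspected[i]) {
        s <- spiro[[i]]
        tt <- ct + 1500
        inst <- advance(inst, "calibration_checked", tt,
                        payload = list(calibrated = !isTRUE(appt$uncalibrated)),
                        model = model)
        if (identical(inst$state, "device_calibration")) {
          tt <- tt + 600
          inst <- advance(inst, "calibration_performed", tt, model = model)
        }
        for (r in seq_len(s$rounds)) {
          tt <- tt + 900
          inst <- advance(inst, "attempts_recorded", tt, model = model)
          last_round <- r == s$rounds
          tt <- tt + 120
          inst <- advance(inst, "session_validated", tt,
                          payload = list(
                            session_valid = if (last_round) TRUE else FALSE,
                            obstructed = isTRUE(s$obstructed)),
                          model = model)
        }
        if (isTRUE(s$obstructed)) {
          tt <- tt + 3 * 86400
          inst <- advance(inst, "tests_reviewed", tt, model = model)
          inst <- advance(inst, "alternatives_ruled_out", tt + 3600,
                          payload = list(copd_confirmed = TRUE), model = model)
          j <- match(i, staged_idx)
          inst <- advance(inst, "staged", tt + 4200,
                          payload = list(refer = isTRUE(staging$refer[j])),
                          model = model)
          final_event <- if (isTRUE(staging$refer[j])) "report_completed"
          else "treatment_defined"
          inst <- advance(inst, final_event, tt + 5400, model = model)
        }
      }
    }
    if (!is_terminal_instance(model, inst)) {
      copd_abort(paste0("replay left instance non-terminal: ", inst$instance_id),
                 "copd_replay_failure")
    }
    instances[[i]] <- inst
    terminal[i] <- inst$state
    t_diag[i] <- as.numeric(difftime(inst$log[[length(inst$log)]]$exited,
                                     appt$request_time, units = "days"))
  }

  engine_call <- ifelse(terminal == "no_show", NA, call)
  results <- tibble(
    patient_id = cohort$patients$patient_id,
    screened = screened,
    screen_positive = screen_positive,
    suspected = suspected,
    terminal_state = terminal,
    engine_obstructed = engine_call,
    true_obstructed = cohort$labels$true_obstructed,
    session_first_valid = map_lgl(spiro, function(s)
      if (is.null(s)) NA else isTRUE(s$first_valid)),
    session_forced = map_lgl(spiro, function(s)
      if (is.null(s)) NA else isTRUE(s$forced)),
    spirometry_rounds = map_dbl(spiro, function(s)
      if (is.null(s)) NA_real_ else s$rounds),
    time_to_outcome_days = t_diag
  )

  kept <- !is.na(results$engine_obstructed)
  confusion <- table(
    engine = factor(results$engine_obstructed[kept], levels = c(TRUE, FALSE),
                    labels = c("obstructed", "clear")),
    truth = factor(results$true_obstructed[kept], levels = c(TRUE, FALSE),
                   labels = c("obstructed", "clear"))
  )
  tp <- confusion["obstructed", "obstructed"]
  fn <- confusion["clear", "obstructed"]
  tn <- confusion["clear", "clear"]
  fp <- confusion["obstructed", "clear"]
  n_diag <- sum(terminal %in% c("copd_diagnosed_primary_care",
                                "referred_to_specialist"))
  metrics <- list(
    n = n,
    no_show_rate = mean(terminal == "no_show"),
    screening_uptake = mean(screened),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    referral_rate = if (n_diag > 0)
      sum(terminal == "referred_to_specialist") / n_diag else NA_real_,
    session_invalid_rate = {
      fv <- results$session_first_valid
      if (any(!is.na(fv))) mean(!fv[!is.na(fv)]) else NA_real_
    },
    forced_session_rate = {
      f <- results$session_forced
      if (any(!is.na(f))) mean(f[!is.na(f)]) else NA_real_
    },
    mean_time_to_outcome_days = mean(t_diag[terminal != "no_show"]),
    median_time_to_outcome_days = median(t_diag[terminal != "no_show"])
  )

  structure(
    list(results = results, confusion = confusion, metrics = metrics,
         staging = staging, instances = instances,
         task_durations = task_duration_report(instances)),
    class = "copd_replay"
  )
}

#' @export
print.copd_replay <- function(x, ...) {
  cat("<copd_replay>", x$metrics$n, "patients\n")
  print(x$confusion)
  cat(sprintf("  sensitivity %.3f | specificity %.3f | no-show %.1f%%\n",
              x$metrics$sensitivity, x$metrics$specificity,
              100 * x$metrics$no_show_rate))
  cat(sprintf("  referral rate %.3f | invalid first sessions %.3f\n",
              x$metrics$referral_rate %||% NA,
              x$metrics$session_invalid_rate %||% NA))
  invisible(x)
}
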