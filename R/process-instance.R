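#' Start a process instance for a patient
#'
#' Creates a traceable process instance in the model's initial state with an
#' opened task-log entry. Every subsequent [advance()] closes the current task
#' (recording its realization time) and opens the next one, so the log is a
#' complete walk through the model.
#'
#' @param model A `copd_process_model` from [load_process_model()].
#' @param patient_id Patient identifier.
#' @param clock Entry timestamp (POSIXct or ISO-8601 string); clocks are
#'   always explicit — nothing reads the wall clock.
#' @param instance_id Optional instance identifier (defaults to
#'   `"pi-<patient_id>"`).
#' @return A `copd_instance` object.
#' @examples
#' model <- load_process_model()
#' inst <- process_start(model, "p1", "2024-03-01T08:00:00Z")
#' inst$state
#' @export
process_start <- function(model, patient_id, clock,
                          instance_id = paste0("pi-", patient_id)) {
  stopifnot(inherits(model, "copd_process_model"))
  clock <- as_utc(clock)
  structure(
    list(
      instance_id = instance_id,
      patient_id = patient_id,
      state = model$initial,
      payload = list(),
      log = list(list(state = model$initial, event = "start",
                      actor = unname(model$actor_of[model$initial]),
                      entered = clock, exited = NA)),
      notifications = list(),
      model_name = model$name
    ),
    class = "copd_instance"
  )
}

is_terminal_instance <- function(model, instance) {
  isTRUE(unname(model$is_terminal[instance$state]))
}

#' Advance a process instance by one event
#'
#' Dispatches `event` from the instance's current state: the payload is merged
#' into the instance payload, the first transition whose guard holds fires, the
#' current task-log entry is closed at `clock`, and a new entry is opened in
#' the target state. Entering `screening_invited` emits a `screening_invite`
#' notification to the patient; entering `suspicion_recorded` notifies both
#' patient and doctor of a probable COPD case.
#'
#' @param instance A `copd_instance`.
#' @param event Event name, defined for the current state.
#' @param clock Timestamp of the event; must not precede the current task's
#'   entry time.
#' @param payload Named list of guard facts (e.g. `list(eligible = TRUE)`).
#' @param model The process model the instance runs under.
#' @return The updated `copd_instance`.
#' @examples
#' model <- load_process_model()
#' inst <- process_start(model, "p1", "2024-03-01T08:00:00Z")
#' inst <- advance(inst, "eligibility_checked", "2024-03-01T08:00:05Z",
#'                 payload = list(eligible = TRUE), model = model)
#' inst$state
#' @export
advance <- function(instance, event, clock, payload = list(),
                    model = load_process_model()) {
  stopifnot(inherits(instance, "copd_instance"))
  clock <- as_utc(clock)
  if (is_terminal_instance(model, instance)) {
    copd_abort(
      paste0("instance ", instance$instance_id, " is terminal (",
             instance$state, ")"),
      "copd_terminal_error"
    )
  }
  last <- instance$log[[length(instance$log)]]
  if (clock < last$entered) {
    copd_abort("event clock precedes current task entry time", "copd_clock_error")
  }

  merged <- modifyList(instance$payload, payload)
  trs <- model$transitions
  idx <- which(trs$from == instance$state & trs$event == event)
  if (length(idx) == 0L) {
    copd_abort(
      paste0("event '", event, "' is not valid in state '", instance$state, "'"),
      "copd_rejected_event"
    )
  }
  fired <- NA_integer_
  for (i in idx) {
    if (guard_holds(model$guards[[trs$guard[i]]], merged)) {
      fired <- i
      break
    }
  }
  if (is.na(fired)) {
    copd_abort(
      paste0("no guard satisfied for event '", event, "' in state '",
             instance$state, "'"),
      "copd_rejected_event"
    )
  }
  to <- trs$to[fired]

  instance$payload <- merged
  instance$log[[length(instance$log)]]$exited <- clock
  entry <- list(state = to, event = event,
                actor = unname(model$actor_of[to]),
                entered = clock, exited = NA)
  if (isTRUE(unname(model$is_terminal[to]))) entry$exited <- clock
  instance$log[[length(instance$log) + 1L]] <- entry
  instance$state <- to

  if (identical(to, "screening_invited")) {
    instance$notifications[[length(instance$notifications) + 1L]] <-
      list(recipient = "patient", kind = "screening_invite",
           scheduled_time = clock, payload_key = "screening_invite_message")
  }
  if (identical(to, "suspicion_recorded")) {
    for (who in c("patient", "doctor")) {
      instance$notifications[[length(instance$notifications) + 1L]] <-
        list(recipient = who, kind = "screening_positive_alert",
             scheduled_time = clock, payload_key = "probable_copd_case")
    }
  }
  instance
}

#' Task log of a process instance
#'
#' @param instance A `copd_instance`.
#' @return A tibble with one row per task-log entry: `instance_id`,
#'   `patient_id`, `state`, `event`, `actor`, `entered`, `exited` (NA while
#'   the task is open).
#' @export
task_log <- function(instance) {
  stopifnot(inherits(instance, "copd_instance"))
  entries <- instance$log
  tibble(
    instance_id = instance$instance_id,
    patient_id = instance$patient_id,
    state = map_chr(entries, "state"),
    event = map_chr(entries, "event"),
    actor = map_chr(entries, "actor"),
    entered = as.POSIXct(vapply(entries, function(e) as.numeric(e$entered),
                                numeric(1)), origin = "1970-01-01", tz = "UTC"),
    exited = as.POSIXct(vapply(entries, function(e) {
      if (length(e$exited) == 1L && is.na(e$exited)) NA_real_ else as.numeric(e$exited)
    }, numeric(1)), origin = "1970-01-01", tz = "UTC")
  )
}

#' Notifications emitted by an instance
#'
#' @param instance A `copd_instance`.
#' @return A tibble of notifications (recipient, kind, scheduled time,
#'   payload key); zero rows if none.
#' @export
notifications <- function(instance) {
  ns <- instance$notifications
  if (length(ns) == 0L) {
    return(tibble(recipient = character(), kind = character(),
                  scheduled_time = as.POSIXct(character(), tz = "UTC"),
                  payload_key = character()))
  }
  tibble(
    recipient = map_chr(ns, "recipient"),
    kind = map_chr(ns, "kind"),
    scheduled_time = as.POSIXct(vapply(ns, function(n) as.numeric(n$scheduled_time),
                                       numeric(1)), origin = "1970-01-01", tz = "UTC"),
    payload_key = map_chr(ns, "payload_key")
  )
}

#' Replay a task log against a process model
#'
#' Independently re-walks the `(event, state)` sequence of a task log through
#' the model's transition graph, verifying that each step is a declared
#' transition from the previous state, and returns the replayed final state.
#' Used as the soundness oracle for instance execution.
#'
#' @param log A task-log tibble from [task_log()] (a single instance).
#' @param model The process model.
#' @return The final state reached by the replay.
#' @export
replay_task_log <- function(log, model = load_process_model()) {
  if (nrow(log) == 0L) copd_abort("empty task log", "copd_replay_error")
  if (!identical(log$state[1], model$initial)) {
    copd_abort("log does not start in the initial state", "copd_replay_error")
  }
  current <- model$initial
  trs <- model$transitions
  if (nrow(log) > 1L) {
    for (i in 2:nrow(log)) {
      ok <- any(trs$from == current & trs$event == log$event[i] &
                  trs$to == log$state[i])
      if (!ok) {
        copd_abort(
          sprintf("log step %d (%s --%s--> %s) is not a model transition",
                  i, current, log$event[i], log$state[i]),
          "copd_replay_error"
        )
      }
      current <- log$state[i]
    }
  }
  current
}

#' Schedule an appointment reminder
#'
#' The reminder is scheduled exactly `lead_hours` before the appointment
#' (default 24 h), the anti-absenteeism measure of the redesigned pathway.
#'
#' @param appointment_time Appointment timestamp.
#' @param lead_hours Lead time in hours.
#' @param patient_id Optional patient id carried in the output.
#' @return A one-row notification tibble.
#' @examples
#' schedule_reminder("2024-03-02T09:00:00Z")
#' @export
schedule_reminder <- function(appointment_time, lead_hours = 24,
                              patient_id = NA_character_) {
  t <- as_utc(appointment_time)
  tibble(
    patient_id = patient_id,
    recipient = "patient",
    kind = "appointment_reminder",
    scheduled_time = t - lead_hours * 3600,
    payload_key = "appointment_reminder_message"
  )
}

#' Nightly appointment sweep
#'
#' At the end of each day the engine consults the day's new appointments,
#' classifies each patient against the opportunistic-screening eligibility rule
#' (strictly over the age cut and not screened within the revalidation window),
#' opens a process instance and sends a screening invitation for each eligible
#' patient, and schedules a reminder ahead of every appointment. Appointments
#' without a usable age are skipped and reported; a patient appearing several
#' times in one sweep is invited at most once, and passing a previous sweep's
#' result as `state` makes the sweep idempotent.
#'
#' @param appointments Tibble with `patient_id`, `age`, `appointment_time`.
#' @param screening_history Tibble with `patient_id`, `last_screening` (date of
#'   the most recent completed screening), or `NULL`.
#' @param clock Sweep timestamp.
#' @param config Engine configuration.
#' @param model Process model for the new instances.
#' @param state A previous sweep result (for idempotent re-runs), or `NULL`.
#' @return A list: `notifications` (tibble), `instances` (list of
#'   `copd_instance` advanced to `screening_invited`), `invited` (tibble of
#'   patient ids invited, cumulative), `reminded` (appointment keys reminded,
#'   cumulative), `skipped` (tibble of skipped records with reasons).
#' @export
nightly_appointment_sweep <- function(appointments, screening_history = NULL,
                                      clock, config = engine_config(),
                                      model = config$process_model,
                                      state = NULL) {
  clock <- as_utc(clock)
  invited <- state$invited %||% tibble(patient_id = character())
  reminded <- state$reminded %||% character()
  notes <- list()
  instances <- list()
  skipped <- list()

  if (nrow(appointments) > 0L) {
    for (i in seq_len(nrow(appointments))) {
      row <- appointments[i, ]
      if (is.na(row$age)) {
        skipped[[length(skipped) + 1L]] <-
          tibble(patient_id = row$patient_id, reason = "missing_age")
        next
      }
      appt_key <- paste0(row$patient_id, "@", format_iso8601(row$appointment_time))
      if (!appt_key %in% reminded) {
        notes[[length(notes) + 1L]] <-
          schedule_reminder(row$appointment_time, config$reminder_lead_hours,
                            patient_id = row$patient_id)
        reminded <- c(reminded, appt_key)
      }
      if (row$patient_id %in% invited$patient_id) next
      last <- NULL
      if (!is.null(screening_history)) {
        hit <- screening_history$last_screening[
          screening_history$patient_id == row$patient_id]
        if (length(hit) > 0L && !all(is.na(hit))) last <- max(hit, na.rm = TRUE)
      }
      elig <- is_eligible_for_screening(row$age, clock, last, config = config)
      if (!elig$eligible) next
      inst <- process_start(model, row$patient_id, clock)
      inst <- advance(inst, "eligibility_checked", clock,
                      payload = list(eligible = TRUE), model = model)
      instances[[length(instances) + 1L]] <- inst
      notes[[length(notes) + 1L]] <- tibble(
        patient_id = row$patient_id, recipient = "patient",
        kind = "screening_invite", scheduled_time = clock,
        payload_key = "screening_invite_message"
      )
      invited <- dplyr::bind_rows(invited, tibble(patient_id = row$patient_id))
    }
  }

  list(
    notifications = if (length(notes)) dplyr::bind_rows(notes) else
      schedule_reminder(clock)[0, ],
    instances = instances,
    invited = invited,
    reminded = reminded,
    skipped = if (length(skipped)) dplyr::bind_rows(skipped) else
      tibble(patient_id = character(), reason = character())
  )
}

#' Per-task duration report
#'
#' Summarises realization times per task across instances — the
#' continuous-improvement view that shows which tasks are slowing the process.
#' Open tasks (no exit timestamp) are excluded from the duration statistics and
#' counted separately.
#'
#' @param instances A list of `copd_instance` objects, or an already-exported
#'   task-log tibble (e.g. from [read_task_log()]).
#' @return A tibble with one row per task: `state`, `n_closed`, `mean_s`,
#'   `median_s`, `max_s`, `n_open`.
#' @export
task_duration_report <- function(instances) {
  logs <- if (is.data.frame(instances)) instances
  else dplyr::bind_rows(lapply(instances, task_log))
  if (nrow(logs) == 0L) {
    return(tibble(state = character(), n_closed = integer(), mean_s = numeric(),
                  median_s = numeric(), max_s = numeric(), n_open = integer()))
  }
  logs |>
    mutate(duration_s = as.numeric(.data$exited) - as.numeric(.data$entered),
           open = is.na(.data$exited)) |>
    group_by(.data$state) |>
    summarise(
      n_closed = sum(!.data$open),
      mean_s = if (any(!.data$open)) mean(.data$duration_s[!.data$open]) else NA_real_,
      median_s = if (any(!.data$open)) median(.data$duration_s[!.data$open]) else NA_real_,
      max_s = if (any(!.data$open)) max(.data$duration_s[!.data$open]) else NA_real_,
      n_open = sum(.data$open),
      .groups = "drop"
    )
}

#' Simulate a random valid walk through the process model
#'
#' From each non-terminal state a random outgoing transition is chosen, a
#' payload satisfying its guard is constructed, and the instance is advanced
#' with a strictly increasing clock. Used to exercise log-walk soundness.
#'
#' @param model Process model.
#' @param seed Integer seed.
#' @param start_time Start timestamp.
#' @param max_steps Safety cap on steps.
#' @return A terminal (or capped) `copd_instance`.
#' @export
random_instance_walk <- function(model = load_process_model(), seed = 1,
                                 start_time = "2024-01-01T00:00:00Z",
                                 max_steps = 200L) {
  set.seed(seed)
  clock <- as_utc(start_time)
  inst <- process_start(model, paste0("walk-", seed), clock)
  trs <- model$transitions
  steps <- 0L
  while (!is_terminal_instance(model, inst) && steps < max_steps) {
    idx <- which(trs$from == inst$state)
    pick <- if (length(idx) == 1L) idx else sample(idx, 1L)
    payload <- guard_payload(model$guards[[trs$guard[pick]]])
    clock <- clock + stats::runif(1, 1, 3600)
    inst <- advance(inst, trs$event[pick], clock, payload = payload, model = model)
    steps <- steps + 1L
  }
  inst
}

#' @export
print.copd_instance <- function(x, ...) {
  cat("<copd_instance>", x$instance_id, "patient", x$patient_id, "\n")
  cat("  state:", x$state, "| log entries:", length(x$log),
      "| notifications:", length(x$notifications), "\n")
  invisible(x)
}
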