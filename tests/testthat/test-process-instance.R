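model <- load_process_model()

test_that("advancing through eligibility sends the screening invitation", {
  inst <- process_start(model, "p1", "2024-03-01T08:00:00Z")
  inst <- advance(inst, "eligibility_checked", "2024-03-01T23:00:00Z",
                  payload = list(eligible = TRUE), model = model)
  expect_equal(inst$state, "screening_invited")
  ns <- notifications(inst)
  expect_equal(ns$kind, "screening_invite")
  expect_equal(ns$recipient, "patient")
})

test_that("a positive screening notifies both patient and doctor", {
  inst <- process_start(model, "p2", "2024-03-01T08:00:00Z")
  inst <- advance(inst, "eligibility_checked", "2024-03-01T23:00:00Z",
                  payload = list(eligible = TRUE), model = model)
  inst <- advance(inst, "screening_done", "2024-03-02T10:00:00Z",
                  payload = list(screening_positive = TRUE), model = model)
  expect_equal(inst$state, "suspicion_recorded")
  ns <- notifications(inst)
  alert <- ns[ns$kind == "screening_positive_alert", ]
  expect_setequal(alert$recipient, c("patient", "doctor"))
})

test_that("terminal instances reject any event and invalid events are rejected unchanged", {
  inst <- process_start(model, "p3", "2024-03-01T08:00:00Z")
  expect_error(advance(inst, "screening_done", "2024-03-01T09:00:00Z",
                       model = model),
               class = "copd_rejected_event")
  # walk to a terminal state
  inst <- advance(inst, "eligibility_checked", "2024-03-01T23:00:00Z",
                  payload = list(eligible = FALSE), model = model)
  inst <- advance(inst, "no_show_timeout", "2024-03-10T08:00:00Z", model = model)
  expect_equal(inst$state, "no_show")
  expect_error(advance(inst, "patient_arrived", "2024-03-11T08:00:00Z",
                       model = model),
               class = "copd_terminal_error")
})

test_that("task logs record nondecreasing timestamps and exactly one open task", {
  inst <- process_start(model, "p4", "2024-03-01T08:00:00Z")
  inst <- advance(inst, "eligibility_checked", "2024-03-01T23:00:00Z",
                  payload = list(eligible = TRUE), model = model)
  inst <- advance(inst, "screening_done", "2024-03-02T10:00:00Z",
                  payload = list(screening_positive = FALSE), model = model)
  log <- task_log(inst)
  expect_true(all(diff(as.numeric(log$entered)) >= 0))
  expect_equal(sum(is.na(log$exited)), 1L)
  expect_error(advance(inst, "patient_arrived", "2024-03-01T00:00:00Z",
                       model = model),
               class = "copd_clock_error")
})

test_that("random valid walks replay to their logged final state", {
  for (s in 1:50) {
    w <- random_instance_walk(model, seed = s)
    log <- task_log(w)
    expect_identical(replay_task_log(log, model), w$state)
    expect_true(all(diff(as.numeric(log$entered)) >= 0))
    # terminal instances have no open task
    expect_equal(sum(is.na(log$exited)), 0L)
  }
})

test_that("reminders are scheduled exactly lead hours before the appointment", {
  t <- as.POSIXct("2024-03-02T09:00:00Z", format = "%Y-%m-%dT%H:%M:%SZ",
                  tz = "UTC")
  r <- schedule_reminder(t, lead_hours = 24)
  expect_equal(as.numeric(t) - as.numeric(r$scheduled_time), 24 * 3600)
  r6 <- schedule_reminder(t, lead_hours = 6)
  expect_equal(as.numeric(t) - as.numeric(r6$scheduled_time), 6 * 3600)
})

test_that("nightly sweep invites exactly the eligible, respecting the 2-year window", {
  cfg <- test_config()
  appts <- tibble::tibble(
    patient_id = c("a", "b", "c"),
    age = c(38, 41, 70),
    appointment_time = as.POSIXct("2024-03-10 09:00:00", tz = "UTC")
  )
  res <- nightly_appointment_sweep(appts, NULL, "2024-03-01T23:00:00Z",
                                   config = cfg)
  invites <- res$notifications[res$notifications$kind == "screening_invite", ]
  expect_setequal(invites$patient_id, c("b", "c"))
  expect_length(res$instances, 2L)

  # screened 18 months ago -> not re-invited
  hist <- tibble::tibble(
    patient_id = "c",
    last_screening = as.POSIXct("2022-09-01", tz = "UTC")
  )
  res2 <- nightly_appointment_sweep(appts, hist, "2024-03-01T23:00:00Z",
                                    config = cfg)
  invites2 <- res2$notifications[res2$notifications$kind == "screening_invite", ]
  expect_setequal(invites2$patient_id, "b")
})

test_that("the sweep is idempotent and skips records missing age", {
  cfg <- test_config()
  appts <- tibble::tibble(
    patient_id = c("a", "a", "b"),
    age = c(55, 55, NA),
    appointment_time = as.POSIXct("2024-03-10 09:00:00", tz = "UTC")
  )
  res <- nightly_appointment_sweep(appts, NULL, "2024-03-01T23:00:00Z",
                                   config = cfg)
  expect_equal(sum(res$notifications$kind == "screening_invite"), 1L)
  expect_equal(res$skipped$reason, "missing_age")
  res2 <- nightly_appointment_sweep(appts, NULL, "2024-03-01T23:00:00Z",
                                    config = cfg, state = res)
  expect_equal(nrow(res2$notifications), 0L)

  empty <- nightly_appointment_sweep(appts[0, ], NULL, "2024-03-01T23:00:00Z",
                                     config = cfg)
  expect_equal(nrow(empty$notifications), 0L)
  expect_length(empty$instances, 0L)
})

test_that("task duration report summarises closed tasks and counts open ones", {
  i1 <- process_start(model, "p1", "2024-03-01T08:00:00Z")
  i1 <- advance(i1, "eligibility_checked", "2024-03-01T08:05:00Z",
                payload = list(eligible = TRUE), model = model)
  i2 <- process_start(model, "p2", "2024-03-01T08:00:00Z")
  i2 <- advance(i2, "eligibility_checked", "2024-03-01T08:15:00Z",
                payload = list(eligible = TRUE), model = model)
  rep <- task_duration_report(list(i1, i2))
  appt <- rep[rep$state == "appointment_requested", ]
  expect_equal(appt$n_closed, 2L)
  expect_equal(appt$mean_s, (300 + 900) / 2)
  expect_equal(appt$max_s, 900)
  open <- rep[rep$state == "screening_invited", ]
  expect_equal(open$n_open, 2L)
  expect_true(is.na(open$mean_s))
  expect_equal(nrow(task_duration_report(list())), 0L)
})
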