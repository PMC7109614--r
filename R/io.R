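# Readers/writers shared by all modules. JSON is the canonical record format;
# CSV is a flat convenience dialect (one row per patient / per attempt).
# All timestamps are ISO-8601 UTC.

#' Write and read patient records
#'
#' @param patients Patients tibble.
#' @param path Output path (`.json` or `.csv` by extension).
#' @return `path` (writer) / a tibble (reader).
#' @export
write_patients <- function(patients, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(patients, path, progress = FALSE)
  } else {
    jsonlite::write_json(patients, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_patients
#' @export
read_patients <- function(path) {
  tbl <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    as_tibble(jsonlite::fromJSON(path))
  }
  required <- c("patient_id", "age", "sex", "height")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0L) {
    copd_abort(paste0("patient records missing field(s): ",
                      paste(missing, collapse = ", ")), "copd_schema_error")
  }
  if (any(!is.na(tbl$age) & tbl$age < 0) ||
      any(!is.na(tbl$height) & tbl$height <= 0)) {
    copd_abort("patient records violate age >= 0 / height > 0", "copd_schema_error")
  }
  if ("weight" %in% names(tbl) && any(!is.na(tbl$weight) & tbl$weight <= 0)) {
    copd_abort("patient records violate weight > 0", "copd_schema_error")
  }
  tbl
}

#' Write and read spirometry sessions
#'
#' CSV is one row per attempt with a `patient_id` (session id) column; JSON
#' nests attempts under each session.
#'
#' @param sessions Attempts tibble (`patient_id`, `attempt`, `fvc`, `fev1`,
#'   optional `fet` and flag columns).
#' @param path Output path (`.json` or `.csv`).
#' @return `path` (writer) / a tibble (reader).
#' @export
write_sessions <- function(sessions, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(sessions, path, progress = FALSE)
  } else {
    nested <- split(sessions[setdiff(names(sessions), "patient_id")],
                    sessions$patient_id)
    obj <- lapply(names(nested), function(id) {
      list(patient_id = id, attempts = nested[[id]])
    })
    jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_sessions
#' @export
read_sessions <- function(path) {
  tbl <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    dplyr::bind_rows(lapply(seq_len(nrow(obj)), function(i) {
      at <- obj$attempts[[i]]
      at$patient_id <- obj$patient_id[i]
      at
    }))
  }
  for (col in c("patient_id", "fvc", "fev1")) {
    if (!col %in% names(tbl)) {
      copd_abort(paste0("session records missing field: ", col),
                 "copd_schema_error")
    }
  }
  as_tibble(tbl)
}

#' Export task logs as JSON Lines
#'
#' One record per task-log entry (instance id, patient id, state, event,
#' actor, ISO-8601 entry/exit timestamps), append-only and replayable.
#'
#' @param instances List of `copd_instance` objects.
#' @param path Output `.jsonl` path.
#' @return `path`, invisibly.
#' @export
write_task_log <- function(instances, path) {
  logs <- dplyr::bind_rows(lapply(instances, task_log))
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_len(nrow(logs))) {
    rec <- list(
      instance_id = logs$instance_id[i],
      patient_id = logs$patient_id[i],
      state = logs$state[i],
      event = logs$event[i],
      actor = logs$actor[i],
      entered = format_iso8601(logs$entered[i]),
      exited = if (is.na(logs$exited[i])) NULL else format_iso8601(logs$exited[i])
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' @rdname write_task_log
#' @export
read_task_log <- function(path) {
  lines <- readLines(path)
  dplyr::bind_rows(lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    tibble(
      instance_id = rec$instance_id, patient_id = rec$patient_id,
      state = rec$state, event = rec$event, actor = rec$actor,
      entered = parse_iso8601(rec$entered),
      exited = if (is.null(rec$exited)) as.POSIXct(NA, tz = "UTC")
      else parse_iso8601(rec$exited)
    )
  }))
}
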