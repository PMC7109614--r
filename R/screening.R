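#' Opportunistic screening eligibility
#'
#' A patient booked for any appointment is invited to COPD screening when they
#' are strictly over the age cut (default 40 years) and have not completed a
#' screening within the revalidation window (default 2 years).
#'
#' @param age Age in years (NA allowed; yields `missing_age`).
#' @param clock Current date/time.
#' @param last_screening Date of the most recent completed screening, or
#'   `NULL`/`NA` if never screened.
#' @param config Engine configuration.
#' @return A list with `eligible` (logical) and `reason` (`"eligible"`,
#'   `"age"`, `"recent_screening"`, or `"missing_age"`).
#' @examples
#' is_eligible_for_screening(41, "2024-03-01T00:00:00Z")$eligible
#' is_eligible_for_screening(40, "2024-03-01T00:00:00Z")$reason
#' @export
is_eligible_for_screening <- function(age, clock, last_screening = NULL,
                                      config = engine_config()) {
  if (length(age) != 1L || is.na(age)) {
    return(list(eligible = FALSE, reason = "missing_age"))
  }
  if (!(age > config$age_cut)) {
    return(list(eligible = FALSE, reason = "age"))
  }
  if (!is.null(last_screening) && !all(is.na(last_screening))) {
    elapsed_years <- as.numeric(difftime(as_utc(clock), as_utc(last_screening),
                                         units = "days")) / 365.25
    if (elapsed_years <= config$revalidation_years) {
      return(list(eligible = FALSE, reason = "recent_screening"))
    }
  }
  list(eligible = TRUE, reason = "eligible")
}

#' Screen a table of patients for eligibility
#'
#' Vectorised, pipe-friendly wrapper over [is_eligible_for_screening()].
#'
#' @param patients Tibble with `patient_id`, `age` and optionally
#'   `last_screening`.
#' @param clock Current date/time.
#' @param config Engine configuration.
#' @return The input with `eligible` and `reason` columns added.
#' @export
screen_eligibility <- function(patients, clock, config = engine_config()) {
  has_hist <- "last_screening" %in% names(patients)
  res <- lapply(seq_len(nrow(patients)), function(i) {
    is_eligible_for_screening(
      patients$age[i], clock,
      if (has_hist) patients$last_screening[i] else NULL,
      config = config
    )
  })
  patients |>
    mutate(eligible = map_lgl(res, "eligible"),
           reason = map_chr(res, "reason"))
}

#' Load a screening questionnaire definition
#'
#' @param path YAML/JSON instrument file with `name`, `cutoff`, and `items`
#'   (each with `key`, `min`, `max`, and display `text`).
#' @return A `copd_instrument` list.
#' @export
load_instrument <- function(path = copd_sys_file("screening_instrument.yaml")) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(doc$items) || length(doc$items) == 0L) {
    copd_abort("instrument has no items", "copd_instrument_error")
  }
  items <- dplyr::bind_rows(lapply(doc$items, function(it) {
    tibble(key = it$key, text = it$text %||% it$key,
           min = it$min %||% 0, max = it$max)
  }))
  if (anyDuplicated(items$key)) {
    copd_abort("duplicate instrument item key", "copd_instrument_error")
  }
  if (!is_scalar_number(doc$cutoff)) {
    copd_abort("instrument cutoff missing", "copd_instrument_error")
  }
  if (doc$cutoff > sum(items$max)) {
    copd_abort("instrument cutoff exceeds the maximum attainable score",
               "copd_instrument_error")
  }
  structure(list(name = doc$name %||% "instrument",
                 source = doc$source %||% "unspecified",
                 cutoff = doc$cutoff, items = items),
            class = "copd_instrument")
}

#' Score a screening questionnaire
#'
#' Answers are matched by item key (order of arrival is irrelevant), each is
#' range-checked against its item definition, and the total is the sum of item
#' scores. The result is positive when the total reaches the instrument cutoff
#' (`total >= cutoff`).
#'
#' @param answers Named list/vector of item answers, or a tibble with `key`
#'   and `answer` columns.
#' @param instrument A `copd_instrument` (default: the bundled screener).
#' @param screening_date Optional date attached to the result.
#' @return A `copd_screening_result` list: `answers` (tibble), `total`,
#'   `positive`, `screening_date`.
#' @examples
#' instr <- load_instrument()
#' score_screening(c(age_band = 2, pack_years_band = 2, dyspnea_exertion = 1,
#'                   chronic_cough_sputum = 1, breathing_episodes = 0), instr)$total
#' @export
score_screening <- function(answers, instrument = load_instrument(),
                            screening_date = NA) {
  if (is.data.frame(answers)) {
    answers <- setNames(as.list(answers$answer), answers$key)
  } else {
    answers <- as.list(answers)
  }
  items <- instrument$items
  missing <- setdiff(items$key, names(answers))
  if (length(missing) > 0L) {
    copd_abort(paste0("missing answer for item: ", missing[1]),
               "copd_scoring_error")
  }
  scores <- numeric(nrow(items))
  for (i in seq_len(nrow(items))) {
    a <- answers[[items$key[i]]]
    if (!is_scalar_number(a) || a < items$min[i] || a > items$max[i]) {
      copd_abort(
        paste0("answer out of range for item '", items$key[i], "': ",
               format(a), " (allowed ", items$min[i], "-", items$max[i], ")"),
        "copd_scoring_error"
      )
    }
    scores[i] <- a
  }
  total <- sum(scores)
  structure(
    list(
      answers = tibble(key = items$key, answer = scores),
      total = total,
      positive = total >= instrument$cutoff,
      instrument = instrument$name,
      screening_date = screening_date
    ),
    class = "copd_screening_result"
  )
}

#' @export
print.copd_screening_result <- function(x, ...) {
  cat("<screening result>", x$instrument, "- total", x$total,
      if (x$positive) "(POSITIVE)" else "(negative)", "\n")
  invisible(x)
}

#' Key-indicator clinical suspicion
#'
#' Clinical suspicion of COPD for a patient over the age cut presenting at
#' least one key indicator: dyspnea, chronic cough, chronic sputum production,
#' recurrent lower respiratory tract infections, exposure to risk factors, or
#' a family history of COPD. Unknown indicator flags (NA) count as absent but
#' are reported so "not asked" is distinguishable from "absent".
#'
#' @param patient One-row tibble (or named list) with `age` and logical
#'   indicator columns among `dyspnea`, `chronic_cough`, `chronic_sputum`,
#'   `recurrent_infections`, `risk_exposure`, `family_history_copd`.
#' @param age_cut Age threshold (strict); default 40, configurable to 35.
#' @return A list: `suspicion` (logical), `indicators` (character vector of
#'   triggering indicators), `unknown` (indicators that were NA).
#' @examples
#' key_indicator_suspicion(list(age = 50, chronic_cough = TRUE))$suspicion
#' @export
key_indicator_suspicion <- function(patient, age_cut = 40) {
  keys <- c("dyspnea", "chronic_cough", "chronic_sputum",
            "recurrent_infections", "risk_exposure", "family_history_copd")
  flags <- lapply(keys, function(k) patient[[k]])
  names(flags) <- keys
  unknown <- keys[vapply(flags, function(f) is.null(f) || is.na(f), logical(1))]
  triggering <- keys[vapply(flags, isTRUE, logical(1))]
  age <- patient[["age"]]
  suspicion <- length(age) == 1L && !is.na(age) && age > age_cut &&
    length(triggering) > 0L
  list(suspicion = suspicion, indicators = triggering, unknown = unknown)
}
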