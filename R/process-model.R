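#' Guard registry for the diagnostic process model
#'
#' Guards are pure predicates over the accumulated instance payload: each guard
#' requires a set of payload fields to hold given logical values, so dispatch
#' is deterministic and guards can be inverted when simulating random walks.
#' A missing payload field counts as `FALSE`.
#'
#' @return A named list of guard definitions; each has a `requires` list of
#'   `field = logical` pairs (empty for the unconditional guard `always`).
#' @export
default_guard_registry <- function() {
  list(
    always                  = list(requires = list()),
    eligible                = list(requires = list(eligible = TRUE)),
    not_eligible            = list(requires = list(eligible = FALSE)),
    screening_positive      = list(requires = list(screening_positive = TRUE)),
    screening_negative      = list(requires = list(screening_positive = FALSE)),
    copd_suspected          = list(requires = list(copd_suspected = TRUE)),
    copd_not_suspected      = list(requires = list(copd_suspected = FALSE)),
    calibrated              = list(requires = list(calibrated = TRUE)),
    uncalibrated            = list(requires = list(calibrated = FALSE)),
    session_valid_obstructed = list(requires = list(session_valid = TRUE, obstructed = TRUE)),
    session_valid_clear     = list(requires = list(session_valid = TRUE, obstructed = FALSE)),
    session_invalid         = list(requires = list(session_valid = FALSE)),
    copd_confirmed          = list(requires = list(copd_confirmed = TRUE)),
    alternative_dx_found    = list(requires = list(copd_confirmed = FALSE)),
    refer                   = list(requires = list(refer = TRUE)),
    no_refer                = list(requires = list(refer = FALSE))
  )
}

guard_holds <- function(guard_def, payload) {
  req <- guard_def$requires
  if (length(req) == 0L) return(TRUE)
  for (f in names(req)) {
    if (!identical(isTRUE(payload[[f]]), req[[f]])) return(FALSE)
  }
  TRUE
}

# Payload that makes a guard true (used by the random-walk simulator).
guard_payload <- function(guard_def) {
  lapply(guard_def$requires, identity)
}

#' Load and validate a diagnostic process model
#'
#' Reads a process definition (states with responsible actors and terminal
#' markers, plus guarded transitions) and validates it: the initial state must
#' exist, every state must be reachable from it, terminal states must have no
#' outgoing transitions, non-terminal states at least one, every guard must
#' resolve in the registry, and `(from, event, guard)` triples must be unique.
#' The bundled default encodes the redesigned primary-care COPD pathway from
#' appointment request through screening, consultation, spirometry,
#' differential diagnosis and staging to its four terminal outcomes
#' (`not_copd`, `copd_diagnosed_primary_care`, `referred_to_specialist`,
#' `no_show`).
#'
#' @param definition Path to a YAML/JSON document, or an equivalent list with
#'   elements `name`, `initial`, `states`, `transitions`. Defaults to the
#'   bundled pathway model.
#' @param guards A guard registry; see [default_guard_registry()].
#' @return A `copd_process_model` object.
#' @examples
#' model <- load_process_model()
#' model$initial
#' nrow(model$transitions)
#' @export
load_process_model <- function(definition = NULL,
                               guards = default_guard_registry()) {
  if (is.null(definition)) definition <- copd_sys_file("process_model.yaml")
  if (is.character(definition) && length(definition) == 1L) {
    definition <- if (grepl("\\.json$", definition, ignore.case = TRUE)) {
      jsonlite::read_json(definition, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(definition)
    }
  }
  if (!is.list(definition)) {
    copd_abort("process definition must be a file path or a list", "copd_model_error")
  }
  for (el in c("initial", "states", "transitions")) {
    if (is.null(definition[[el]])) {
      copd_abort(paste0("process definition missing element: ", el), "copd_model_error")
    }
  }

  states <- dplyr::bind_rows(lapply(definition$states, function(s) {
    tibble(name = s$name, actor = s$actor %||% "system",
           terminal = isTRUE(s$terminal))
  }))
  transitions <- dplyr::bind_rows(lapply(definition$transitions, function(tr) {
    tibble(from = tr$from, event = tr$event,
           guard = tr$guard %||% "always", to = tr$to)
  }))

  if (anyDuplicated(states$name)) {
    copd_abort(paste0("duplicate state: ",
                      states$name[duplicated(states$name)][1]), "copd_model_error")
  }
  if (!definition$initial %in% states$name) {
    copd_abort(paste0("initial state not declared: ", definition$initial),
               "copd_model_error")
  }
  bad_actor <- setdiff(unique(states$actor), c("patient", "doctor", "nurse", "system"))
  if (length(bad_actor) > 0L) {
    copd_abort(paste0("unknown actor label: ", bad_actor[1]), "copd_model_error")
  }
  for (col in c("from", "to")) {
    unknown <- setdiff(unique(transitions[[col]]), states$name)
    if (length(unknown) > 0L) {
      copd_abort(paste0("transition references undeclared state: ", unknown[1]),
                 "copd_model_error")
    }
  }
  unknown_guard <- setdiff(unique(transitions$guard), names(guards))
  if (length(unknown_guard) > 0L) {
    copd_abort(paste0("unknown guard: ", unknown_guard[1]), "copd_model_error")
  }
  key <- paste(transitions$from, transitions$event, transitions$guard)
  if (anyDuplicated(key)) {
    copd_abort(paste0("duplicate transition: ", key[duplicated(key)][1]),
               "copd_model_error")
  }

  terminal_states <- states$name[states$terminal]
  bad_terminal <- intersect(unique(transitions$from), terminal_states)
  if (length(bad_terminal) > 0L) {
    copd_abort(paste0("terminal state has outgoing transition: ", bad_terminal[1]),
               "copd_model_error")
  }
  no_exit <- setdiff(setdiff(states$name, terminal_states), unique(transitions$from))
  if (length(no_exit) > 0L) {
    copd_abort(paste0("non-terminal state has no outgoing transition: ", no_exit[1]),
               "copd_model_error")
  }

  unreachable <- setdiff(states$name, reachable_states(definition$initial, transitions))
  if (length(unreachable) > 0L) {
    copd_abort(paste0("state unreachable from initial: ",
                      paste(unreachable, collapse = ", ")), "copd_model_error")
  }

  structure(
    list(
      name = definition$name %||% "process-model",
      initial = definition$initial,
      states = states,
      transitions = transitions,
      guards = guards,
      actor_of = setNames(states$actor, states$name),
      is_terminal = setNames(states$terminal, states$name)
    ),
    class = "copd_process_model"
  )
}

# Breadth-first reachability over the transition graph.
reachable_states <- function(initial, transitions) {
  seen <- initial
  frontier <- initial
  while (length(frontier) > 0L) {
    nxt <- unique(transitions$to[transitions$from %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  seen
}

#' @export
print.copd_process_model <- function(x, ...) {
  cat("<copd_process_model>", x$name, "\n")
  cat("  states:", nrow(x$states),
      "(", sum(x$states$terminal), "terminal ) | transitions:",
      nrow(x$transitions), "\n")
  cat("  initial:", x$initial, "\n")
  invisible(x)
}
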