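#' Tidy a replay result
#'
#' @param x A `copd_replay`.
#' @param ... Unused.
#' @return The per-patient results tibble.
#' @method tidy copd_replay
#' @export
tidy.copd_replay <- function(x, ...) x$results

#' One-row summary of a replay
#'
#' @param x A `copd_replay`.
#' @param ... Unused.
#' @return A one-row tibble of the replay metrics.
#' @method glance copd_replay
#' @export
glance.copd_replay <- function(x, ...) {
  as_tibble(x$metrics[!vapply(x$metrics, is.null, logical(1))])
}

#' Tidy a spirometry session
#'
#' @param x A `copd_session`.
#' @param ... Unused.
#' @return A one-row tibble of the session verdict.
#' @method tidy copd_session
#' @export
tidy.copd_session <- function(x, ...) {
  tibble(
    valid = x$valid, calibrated = x$calibrated, reproducible = x$reproducible,
    n_acceptable = x$n_acceptable, delta_fvc = x$delta_fvc,
    delta_fev1 = x$delta_fev1, best_fvc = x$best_fvc, best_fev1 = x$best_fev1,
    ratio = x$ratio, mode = x$mode, threshold = x$threshold,
    obstructed = x$obstructed, reason = x$reason
  )
}

#' Tidy a screening result
#'
#' @param x A `copd_screening_result`.
#' @param ... Unused.
#' @return The per-item answers with the total and verdict attached.
#' @method tidy copd_screening_result
#' @export
tidy.copd_screening_result <- function(x, ...) {
  mutate(x$answers, total = x$total, positive = x$positive)
}

#' Plot the terminal-state mix of a replay
#'
#' @param object A `copd_replay`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot copd_replay
#' @export
autoplot.copd_replay <- function(object, ...) {
  df <- object$results |>
    dplyr::count(.data$terminal_state, .data$true_obstructed)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$terminal_state, y = .data$n,
                                   fill = .data$true_obstructed)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "terminal state", y = "patients",
                  fill = "truly obstructed",
                  title = "End-to-end outcomes vs ground truth") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 25, hjust = 1))
}

#' Plot per-task durations
#'
#' @param report A tibble from [task_duration_report()].
#' @return A ggplot showing mean task realization times.
#' @export
plot_task_durations <- function(report) {
  df <- filter(report, !is.na(.data$mean_s))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$state, .data$mean_s),
                                   y = .data$mean_s / 60)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean task time (minutes)",
                  title = "Task realization times") +
    ggplot2::theme_minimal()
}

#' Plot a differential-diagnosis ranking
#'
#' @param ranking A tibble from [suggest_differentials()].
#' @return A ggplot of match scores by diagnosis.
#' @export
plot_differentials <- function(ranking) {
  ggplot2::ggplot(ranking,
                  ggplot2::aes(x = stats::reorder(.data$diagnosis, .data$score),
                               y = .data$score)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::coord_flip() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "Jaccard match score",
                  title = "Differential-diagnosis suggestions") +
    ggplot2::theme_minimal()
}
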