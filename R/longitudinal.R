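#' Longitudinal series of photographic grades for one eye
#'
#' Repeated fundus photography over follow-up lets treatment effects be
#' read off the ghost structure: a ghost image that collapses to a single
#' image after surgery documents resolution of the nystagmus.
#'
#' @param eye_id identifier.
#' @param sessions data frame with columns `session_date` (coercible to
#'   `Date`) and `amplitude_grade` (0-3), optionally `direction_class`.
#' @return An object of class `longitudinal_series` (sessions sorted and
#'   strictly increasing in date).
#' @export
longitudinal_series <- function(eye_id, sessions) {
  check_columns(sessions, c("session_date", "amplitude_grade"), "sessions")
  sessions$session_date <- as.Date(sessions$session_date)
  if (anyNA(sessions$session_date))
    stop_ghostgrade("`session_date` must be ISO-8601 dates", "invalid_parameter")
  sessions <- sessions[order(sessions$session_date), , drop = FALSE]
  if (any(diff(sessions$session_date) <= 0))
    stop_ghostgrade("sessions must be strictly increasing in date",
                    "invalid_parameter")
  if (!all(sessions$amplitude_grade %in% 0:3))
    stop_ghostgrade("amplitude grades must be 0-3", "invalid_parameter")
  rownames(sessions) <- NULL
  structure(list(eye_id = as.character(eye_id), sessions = sessions),
            class = "longitudinal_series")
}

#' Compare consecutive imaging sessions of one eye
#'
#' For each consecutive pair of sessions reports the amplitude-grade
#' delta, whether detection status changed, and (when recorded) whether
#' the direction class changed. The series-level flags: `resolved` when
#' the last session is grade 0 after an earlier nonzero grade, and
#' `intermittent` when detection toggles more than once across the series
#' (the paroxysmal pattern in which nystagmus appears in only some of the
#' images).
#'
#' @param series a [longitudinal_series()] (or `eye_id` plus a sessions
#'   data frame, passed through).
#' @return A list of class `session_comparison` with `eye_id`,
#'   `intervals` (data frame: `from`, `to`, `grade_delta`,
#'   `detection_changed`, `direction_changed`), `resolved`,
#'   `intermittent`.
#' @export
compare_sessions <- function(series) {
  if (!inherits(series, "longitudinal_series"))
    stop_ghostgrade("`series` must be a longitudinal_series",
                    "invalid_parameter")
  s <- series$sessions
  if (nrow(s) < 2)
    stop_ghostgrade("need at least 2 sessions to compare",
                    "insufficient_series")
  g <- s$amplitude_grade
  i <- seq_len(nrow(s) - 1)
  dirch <- if ("direction_class" %in% names(s))
    s$direction_class[i + 1] != s$direction_class[i] else NA
  intervals <- data.frame(
    from = s$session_date[i], to = s$session_date[i + 1],
    grade_delta = g[i + 1] - g[i],
    detection_changed = (g[i + 1] > 0) != (g[i] > 0),
    direction_changed = dirch)
  detected_runs <- rle(g > 0)$lengths
  structure(list(
    eye_id = series$eye_id, intervals = intervals,
    resolved = g[length(g)] == 0 && any(g[-length(g)] > 0),
    intermittent = length(detected_runs) >= 3),
    class = "session_comparison")
}

#' @export
print.session_comparison <- function(x, ...) {
  cat(sprintf("<session_comparison> %s: %d interval(s)\n", x$eye_id,
              nrow(x$intervals)))
  print(x$intervals, row.names = FALSE)
  cat(sprintf("  resolved: %s   intermittent: %s\n", x$resolved,
              x$intermittent))
  invisible(x)
}
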