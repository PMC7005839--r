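#' Session configuration for a schedule of reinforcement
#'
#' Bundles the timing and schedule parameters of a single operant session.
#' Self-administration (fixed-ratio) sessions are composed of two pellet
#' periods separated by a pellet-free period; every pellet opens a 10-s
#' time-out during which presses are recorded but do not count toward the
#' ratio. The default FR structure is the long protocol, 25 min + 10 min +
#' 25 min (1 h); `protocol = "short"` gives 55 min + 10 min + 55 min (2 h).
#'
#' @param session_kind One of `"fr"`, `"pr"`, `"shock"`.
#' @param fixed_ratio Presses per pellet (FR1, FR5, ...). Also the block
#'   size of the shock session.
#' @param protocol `"long"` (25/10/25 min) or `"short"` (55/10/55 min);
#'   ignored when the three period durations are given explicitly.
#' @param pellet_period_1_s,pellet_free_s,pellet_period_2_s FR period
#'   durations in seconds. `pellet_free_s` and `pellet_period_2_s` may be 0
#'   to model a single-period session.
#' @param timeout_s Post-pellet time-out duration in seconds (default 10).
#' @param pr_max_duration_s Maximum PR session duration (default 5 h).
#' @param pr_inactivity_limit_s PR session ends after this long with no
#'   lever response (default 1 h).
#' @param shock_session_duration_s Shock-test duration (default 50 min).
#' @param shock_fifth_response_window_s After the 4th response of a block,
#'   the block is reinitiated if the 5th response does not occur within
#'   this window (default 60 s).
#' @return A `session_config` list.
#' @examples
#' session_config("fr", fixed_ratio = 5)
#' session_config("pr")
#' @export
session_config <- function(session_kind = c("fr", "pr", "shock"),
                           fixed_ratio = 5L,
                           protocol = c("long", "short"),
                           pellet_period_1_s = NULL,
                           pellet_free_s = NULL,
                           pellet_period_2_s = NULL,
                           timeout_s = 10,
                           pr_max_duration_s = 5 * 3600,
                           pr_inactivity_limit_s = 3600,
                           shock_session_duration_s = 50 * 60,
                           shock_fifth_response_window_s = 60) {
  session_kind <- match.arg(session_kind)
  protocol <- match.arg(protocol)
  pellet <- if (protocol == "long") 25 * 60 else 55 * 60
  if (is.null(pellet_period_1_s)) pellet_period_1_s <- pellet
  if (is.null(pellet_free_s)) pellet_free_s <- 10 * 60
  if (is.null(pellet_period_2_s)) pellet_period_2_s <- pellet
  stopifnot(
    is.numeric(fixed_ratio), length(fixed_ratio) == 1L,
    fixed_ratio >= 1, fixed_ratio == floor(fixed_ratio),
    pellet_period_1_s > 0, pellet_free_s >= 0, pellet_period_2_s >= 0,
    timeout_s > 0, pr_max_duration_s > 0, pr_inactivity_limit_s > 0,
    shock_session_duration_s > 0, shock_fifth_response_window_s > 0
  )
  structure(
    list(
      session_kind = session_kind,
      fixed_ratio = as.integer(fixed_ratio),
      pellet_period_1_s = pellet_period_1_s,
      pellet_free_s = pellet_free_s,
      pellet_period_2_s = pellet_period_2_s,
      timeout_s = timeout_s,
      pr_max_duration_s = pr_max_duration_s,
      pr_inactivity_limit_s = pr_inactivity_limit_s,
      shock_session_duration_s = shock_session_duration_s,
      shock_fifth_response_window_s = shock_fifth_response_window_s
    ),
    class = "session_config"
  )
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config>", x$session_kind, "FR", x$fixed_ratio, "\n")
  if (x$session_kind == "fr") {
    cat("  periods (s):", x$pellet_period_1_s, "/", x$pellet_free_s, "/",
        x$pellet_period_2_s, "; timeout", x$timeout_s, "s\n")
  }
  invisible(x)
}

#' Timed lever-press stream
#'
#' A press stream is the raw behavioral input to a schedule state machine:
#' an ordered record of lever presses, each with a time (seconds from
#' session start) and the lever pressed. Only active-lever presses can ever
#' count toward a ratio; inactive presses are recorded for the activity
#' discrimination measure.
#'
#' @param time_s Numeric vector of press times (seconds, nondecreasing, >= 0).
#' @param lever Character vector, `"active"` or `"inactive"`, recycled.
#' @return A `press_stream` data.frame with columns `time_s`, `lever`.
#' @examples
#' press_stream(c(0, 1.5, 3), c("active", "active", "inactive"))
#' @export
press_stream <- function(time_s = numeric(), lever = "active") {
  stopifnot(is.numeric(time_s), all(time_s >= 0), !is.unsorted(time_s))
  lever <- rep_len(as.character(lever), length(time_s))
  stopifnot(all(lever %in% c("active", "inactive")))
  structure(
    data.frame(time_s = as.numeric(time_s), lever = lever,
               stringsAsFactors = FALSE),
    class = c("press_stream", "data.frame")
  )
}
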