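#' @keywords internal
EVENT_TYPES <- c("period_start", "period_end", "timeout_start", "timeout_end",
                 "active_press", "inactive_press", "pellet", "shock",
                 "session_end")

# ordering of simultaneous events: a time-out or period closes before the
# press that falls exactly on its boundary; a pellet/shock follows the press
# that triggered it; the time-out opens after its pellet.
.event_rank <- c(period_end = 1, period_start = 2, timeout_end = 3,
                 active_press = 4, inactive_press = 4, shock = 5,
                 pellet = 6, timeout_start = 7, session_end = 8)

new_event_log <- function(time_s, event_type, countable,
                          mouse_id = NA_character_, session_index = NA_integer_,
                          session_kind, config) {
  ord <- order(time_s, .event_rank[event_type], seq_along(time_s))
  df <- data.frame(
    mouse_id = mouse_id,
    session_index = as.integer(session_index),
    session_kind = session_kind,
    time_s = as.numeric(time_s)[ord],
    event_type = as.character(event_type)[ord],
    countable = as.logical(countable)[ord],
    stringsAsFactors = FALSE
  )
  structure(df, class = c("event_log", "data.frame"),
            config = config)
}

#' @export
print.event_log <- function(x, ...) {
  cat("<event_log>", nrow(x), "events;", x$session_kind[1], "session;",
      count_reinforcers(x), "pellets\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Event counts from an event log
#'
#' `count_reinforcers()` counts pellet deliveries, `count_shocks()` counts
#' footshocks, `count_pellet_free_active()` counts non-reinforced active
#' presses made during the pellet-free period (the persistence measure),
#' and `count_presses()` counts presses on one lever.
#'
#' @param log An `event_log`.
#' @param lever `"active"` or `"inactive"` (for `count_presses`).
#' @return A single integer.
#' @export
count_reinforcers <- function(log) {
  sum(log$event_type == "pellet")
}

#' @rdname count_reinforcers
#' @export
count_shocks <- function(log) {
  sum(log$event_type == "shock")
}

#' @rdname count_reinforcers
#' @export
count_presses <- function(log, lever = c("active", "inactive")) {
  lever <- match.arg(lever)
  sum(log$event_type == paste0(lever, "_press"))
}

#' @rdname count_reinforcers
#' @export
count_pellet_free_active <- function(log) {
  cfg <- attr(log, "config")
  if (is.null(cfg) || cfg$session_kind != "fr" || cfg$pellet_free_s <= 0)
    return(0L)
  t0 <- cfg$pellet_period_1_s
  t1 <- t0 + cfg$pellet_free_s
  sum(log$event_type == "active_press" & log$time_s >= t0 & log$time_s < t1)
}

#' Validate event-log invariants
#'
#' Checks the structural invariants of an event log: nondecreasing times,
#' no pellet inside the pellet-free period, nothing after session end, FR
#' ratio consistency (each pellet preceded by exactly `fixed_ratio`
#' countable presses since the previous pellet), and that presses inside a
#' time-out or the pellet-free period are non-countable.
#'
#' @param log An `event_log`.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_event_log <- function(log) {
  stopifnot(inherits(log, "event_log"))
  if (is.unsorted(log$time_s)) stop("event times are not nondecreasing")
  cfg <- attr(log, "config")
  t_end <- log$time_s[log$event_type == "session_end"]
  if (length(t_end) != 1L) stop("log must contain exactly one session_end")
  bad <- log$event_type %in% c("pellet", "shock") & log$time_s > t_end
  if (any(bad)) stop("pellet/shock after session end")
  if (!is.null(cfg) && cfg$session_kind == "fr") {
    if (cfg$pellet_free_s > 0) {
      f0 <- cfg$pellet_period_1_s; f1 <- f0 + cfg$pellet_free_s
      pel <- log$time_s[log$event_type == "pellet"]
      if (any(pel >= f0 & pel < f1)) stop("pellet inside pellet-free period")
      in_free <- log$event_type == "active_press" &
        log$time_s >= f0 & log$time_s < f1
      if (any(log$countable[in_free])) stop("countable press in pellet-free period")
    }
    # ratio consistency: walk pellets against countable presses
    is_cp <- log$event_type == "active_press" & log$countable %in% TRUE
    cum_cp <- cumsum(is_cp)
    at_pellet <- cum_cp[log$event_type == "pellet"]
    if (length(at_pellet) &&
        !all(diff(c(0L, at_pellet)) == cfg$fixed_ratio))
      stop("pellet not preceded by exactly fixed_ratio countable presses")
    # presses inside a time-out are non-countable (the triggering press
    # shares the pellet's timestamp and precedes the timeout_start row)
    to_rows <- which(log$event_type == "timeout_start")
    for (r in to_rows) {
      ts <- log$time_s[r]
      inside <- log$event_type == "active_press" &
        seq_len(nrow(log)) > r & log$time_s < ts + cfg$timeout_s
      if (any(log$countable[inside])) stop("countable press inside time-out")
    }
  }
  invisible(TRUE)
}
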