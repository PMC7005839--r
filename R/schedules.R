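#' Run a fixed-ratio self-administration session
#'
#' Deterministic state machine for the FR schedule: during the two pellet
#' periods every `fixed_ratio`-th countable active press delivers a pellet
#' and opens a time-out of `timeout_s` seconds. Presses inside a time-out
#' or the pellet-free period are recorded but non-countable; the pellet-free
#' period delivers nothing. Time-out intervals are half-open
#' `[t_pellet, t_pellet + timeout_s)`: a press exactly at the time-out end
#' is countable. The ratio counter persists across the pellet-free period.
#'
#' @param stream A [press_stream()].
#' @param config A [session_config()] with `session_kind = "fr"`.
#' @param mouse_id,session_index Metadata carried into the log.
#' @return An `event_log`. Presses at or after session end are dropped with
#'   a warning.
#' @examples
#' cfg <- session_config("fr", fixed_ratio = 5, pellet_period_1_s = 60,
#'                       pellet_free_s = 0, pellet_period_2_s = 0)
#' log <- run_fr_session(press_stream(0:29), cfg)
#' count_reinforcers(log)  # 2, at t = 4 and t = 18
#' @export
run_fr_session <- function(stream, config,
                           mouse_id = NA_character_,
                           session_index = NA_integer_) {
  stopifnot(inherits(config, "session_config"), config$session_kind == "fr")
  f0 <- config$pellet_period_1_s
  f1 <- f0 + config$pellet_free_s
  t_end <- f1 + config$pellet_period_2_s
  has_free <- config$pellet_free_s > 0

  times <- stream$time_s
  lever <- stream$lever
  late <- times >= t_end
  if (any(late)) {
    warning(sum(late), " press(es) at or beyond session end dropped")
    times <- times[!late]; lever <- lever[!late]
  }

  n <- length(times)
  # worst case: every press a countable pellet trigger -> press+pellet+2 timeouts
  ev_t <- numeric(4L * n + 8L)
  ev_y <- character(4L * n + 8L)
  ev_c <- logical(4L * n + 8L)
  k <- 0L

  active <- lever == "active"
  fr <- config$fixed_ratio
  to <- config$timeout_s
  counter <- 0L
  timeout_until <- -Inf
  for (i in seq_len(n)) {
    t <- times[i]
    if (!active[i]) {
      k <- k + 1L
      ev_t[k] <- t; ev_y[k] <- "inactive_press"; ev_c[k] <- FALSE
      next
    }
    countable <- !(has_free && t >= f0 && t < f1) && t >= timeout_until
    k <- k + 1L
    ev_t[k] <- t; ev_y[k] <- "active_press"; ev_c[k] <- countable
    if (countable) {
      counter <- counter + 1L
      if (counter == fr) {
        counter <- 0L
        timeout_until <- t + to
        ev_t[k + 1L] <- t; ev_y[k + 1L] <- "pellet"; ev_c[k + 1L] <- NA
        ev_t[k + 2L] <- t; ev_y[k + 2L] <- "timeout_start"; ev_c[k + 2L] <- NA
        ev_t[k + 3L] <- min(timeout_until, t_end)
        ev_y[k + 3L] <- "timeout_end"; ev_c[k + 3L] <- NA
        k <- k + 3L
      }
    }
  }

  add <- function(t, y) {
    k <<- k + 1L
    ev_t[k] <<- t; ev_y[k] <<- y; ev_c[k] <<- NA
  }
  add(0, "period_start")
  if (has_free) {
    add(f0, "period_end")
    add(f0, "period_start")
    add(f1, "period_end")
    if (config$pellet_period_2_s > 0) {
      add(f1, "period_start")
      add(t_end, "period_end")
    }
  } else {
    add(f0, "period_end")
  }
  add(t_end, "session_end")

  new_event_log(ev_t[seq_len(k)], ev_y[seq_len(k)], ev_c[seq_len(k)],
                mouse_id, session_index, "fr", config)
}

#' Run a progressive-ratio session
#'
#' The response requirement per pellet escalates along `series`; the last
#' completed requirement is the breaking point. The session ends at
#' `pr_max_duration_s`, or when no lever response occurs within
#' `pr_inactivity_limit_s`, or when the series is exhausted. Every active
#' press counts (the PR session has no pellet-free sub-structure and no
#' post-pellet ratio suppression).
#'
#' The `policy` is a response-emitting callback: it is called with a
#' context list (`time`, `ratio_index`, `requirement`, `presses_done`,
#' `pellets`) and must return the waiting time in seconds until the next
#' active press, or `Inf` to stop responding for good. Alternatively a
#' nondecreasing numeric vector of press times may be passed directly; it
#' is processed with identical semantics on a faster vectorized path.
#'
#' @param policy Callback as described, e.g. [policy_fixed_presses()], or
#'   a numeric vector of press times.
#' @param series Requirement series, default [build_pr_series()].
#' @param config A [session_config()] with `session_kind = "pr"`.
#' @param mouse_id,session_index Metadata carried into the log.
#' @return An `event_log`; `count_reinforcers()` gives the number of
#'   completed ratios and [breaking_point()] the breaking point.
#' @examples
#' log <- run_pr_session(policy_fixed_presses(18), session_config("pr"))
#' count_reinforcers(log)  # 3: requirements 1, 5 and 12 completed
#' @export
run_pr_session <- function(policy, config = session_config("pr"),
                           series = build_pr_series(),
                           mouse_id = NA_character_,
                           session_index = NA_integer_) {
  stopifnot(inherits(config, "session_config"), config$session_kind == "pr",
            is.function(policy) || is.numeric(policy))
  max_t <- config$pr_max_duration_s
  inact <- config$pr_inactivity_limit_s
  if (is.numeric(policy)) {
    return(.run_pr_vector(policy, series, inact, max_t, config,
                          mouse_id, session_index))
  }

  ev_t <- numeric(1024L); ev_y <- character(1024L); ev_c <- logical(1024L)
  k <- 0L
  add <- function(t, y, c) {
    if (k == length(ev_t)) {
      length(ev_t) <<- 2L * k; length(ev_y) <<- 2L * k; length(ev_c) <<- 2L * k
    }
    k <<- k + 1L
    ev_t[k] <<- t; ev_y[k] <<- y; ev_c[k] <<- c
  }

  t <- 0; last_resp <- 0
  ridx <- 1L; done <- 0L; presses <- 0L
  t_end <- max_t
  add(0, "period_start", NA)
  repeat {
    if (ridx > length(series)) { t_end <- min(t, max_t); break }
    ctx <- list(time = t, ratio_index = ridx, requirement = series[[ridx]],
                presses_done = presses, pellets = done)
    dt <- policy(ctx)
    stopifnot(is.numeric(dt), length(dt) == 1L, dt >= 0)
    if (!is.finite(dt) || (t + dt) - last_resp >= inact) {
      t_end <- min(last_resp + inact, max_t)
      break
    }
    t <- t + dt
    if (t >= max_t) { t_end <- max_t; break }
    add(t, "active_press", TRUE)
    last_resp <- t
    presses <- presses + 1L
    if (presses == series[[ridx]]) {
      add(t, "pellet", NA)
      done <- done + 1L
      ridx <- ridx + 1L
      presses <- 0L
    }
  }
  add(t_end, "period_end", NA)
  add(t_end, "session_end", NA)
  new_event_log(ev_t[seq_len(k)], ev_y[seq_len(k)], ev_c[seq_len(k)],
                mouse_id, session_index, "pr", config)
}

# vectorized PR walk for a precomputed press-time vector: identical
# semantics to the callback loop (inactivity checked before the time cap,
# series exhaustion ends the session at the completing press)
.run_pr_vector <- function(v, series, inact, max_t, config,
                           mouse_id, session_index) {
  stopifnot(all(v >= 0), !is.unsorted(v))
  ended <- NULL
  cut_inact <- which(diff(c(0, v)) >= inact)[1]
  cut_cap <- which(v >= max_t)[1]
  if (!is.na(cut_inact) && (is.na(cut_cap) || cut_inact <= cut_cap)) {
    last <- if (cut_inact > 1) v[cut_inact - 1L] else 0
    v <- v[seq_len(cut_inact - 1L)]
    ended <- min(last + inact, max_t)
  } else if (!is.na(cut_cap)) {
    v <- v[seq_len(cut_cap - 1L)]
    ended <- max_t
  }
  cs <- cumsum(series)
  if (length(v) >= cs[length(series)]) {     # series exhausted
    v <- v[seq_len(cs[length(series)])]
    ended <- v[length(v)]
  }
  if (is.null(ended)) {
    last <- if (length(v)) v[length(v)] else 0
    ended <- min(last + inact, max_t)
  }
  pel_t <- v[cs[cs <= length(v)]]
  ev_t <- c(0, v, pel_t, ended, ended)
  ev_y <- c("period_start", rep("active_press", length(v)),
            rep("pellet", length(pel_t)), "period_end", "session_end")
  ev_c <- c(NA, rep(TRUE, length(v)), rep(NA, length(pel_t)), NA, NA)
  new_event_log(ev_t, ev_y, ev_c, mouse_id, session_index, "pr", config)
}

#' PR response policies
#'
#' Ready-made callbacks for [run_pr_session()]. `policy_fixed_presses()`
#' emits exactly `n` presses at a constant rate then goes silent.
#' `policy_motivated()` presses with exponential inter-press intervals at
#' `rate_per_min` as long as the current requirement does not exceed
#' `motivation_cap`, then quits; it models an animal whose willingness to
#' work has a ceiling, mapping the latent cap directly onto the breaking
#' point. `policy_unbounded()` never stops.
#'
#' @param n Number of presses to emit.
#' @param rate_per_min Press rate, presses per minute.
#' @param motivation_cap Largest requirement the animal will work through.
#' @return A function suitable as the `policy` of [run_pr_session()].
#' @export
policy_fixed_presses <- function(n, rate_per_min = 60) {
  emitted <- 0L
  function(ctx) {
    if (emitted >= n) return(Inf)
    emitted <<- emitted + 1L
    60 / rate_per_min
  }
}

#' @rdname policy_fixed_presses
#' @export
policy_motivated <- function(motivation_cap, rate_per_min = 60) {
  force(motivation_cap); force(rate_per_min)
  function(ctx) {
    if (ctx$requirement > motivation_cap) return(Inf)
    stats::rexp(1, rate_per_min / 60)
  }
}

#' @rdname policy_fixed_presses
#' @export
policy_unbounded <- function(rate_per_min = 60) {
  function(ctx) 60 / rate_per_min
}

#' Run a punished (footshock) session
#'
#' FR5-with-punishment compulsivity test: within each block of countable
#' active presses, the 4th press delivers a footshock only (no pellet) and
#' the 5th delivers a footshock plus a pellet followed by a 10-s time-out.
#' If the 5th response does not occur within
#' `shock_fifth_response_window_s` (60 s) of the 4th, the block is
#' reinitiated: the counter returns to 0 and the 4th press of the new block
#' delivers a shock again. The session is a single continuous period of
#' `shock_session_duration_s` (50 min); presses inside a time-out are
#' recorded but non-countable.
#'
#' @inheritParams run_fr_session
#' @param config A [session_config()] with `session_kind = "shock"`.
#' @return An `event_log`; `count_shocks()` gives the compulsivity score.
#' @examples
#' cfg <- session_config("shock")
#' log <- run_shock_session(press_stream(c(0, 1, 2, 3)), cfg)
#' count_shocks(log)  # 1: shock at the 4th press, no pellet
#' @export
run_shock_session <- function(stream, config,
                              mouse_id = NA_character_,
                              session_index = NA_integer_) {
  stopifnot(inherits(config, "session_config"),
            config$session_kind == "shock")
  t_end <- config$shock_session_duration_s
  window <- config$shock_fifth_response_window_s
  fr <- config$fixed_ratio

  times <- stream$time_s
  lever <- stream$lever
  late <- times >= t_end
  if (any(late)) {
    warning(sum(late), " press(es) at or beyond session end dropped")
    times <- times[!late]; lever <- lever[!late]
  }

  n <- length(times)
  ev_t <- numeric(5L * n + 4L)
  ev_y <- character(5L * n + 4L)
  ev_c <- logical(5L * n + 4L)
  k <- 0L

  active <- lever == "active"
  to <- config$timeout_s
  counter <- 0L
  timeout_until <- -Inf
  t4 <- -Inf  # time of the 4th response of the current block
  for (i in seq_len(n)) {
    t <- times[i]
    if (!active[i]) {
      k <- k + 1L
      ev_t[k] <- t; ev_y[k] <- "inactive_press"; ev_c[k] <- FALSE
      next
    }
    countable <- t >= timeout_until
    k <- k + 1L
    ev_t[k] <- t; ev_y[k] <- "active_press"; ev_c[k] <- countable
    if (!countable) next
    if (counter == fr - 1L && t >= t4 + window) {
      counter <- 0L  # 5th response too late: block reinitiated
    }
    counter <- counter + 1L
    if (counter == fr - 1L) {
      k <- k + 1L
      ev_t[k] <- t; ev_y[k] <- "shock"; ev_c[k] <- NA
      t4 <- t
    } else if (counter == fr) {
      timeout_until <- t + to
      ev_t[k + 1L] <- t; ev_y[k + 1L] <- "shock"; ev_c[k + 1L] <- NA
      ev_t[k + 2L] <- t; ev_y[k + 2L] <- "pellet"; ev_c[k + 2L] <- NA
      ev_t[k + 3L] <- t; ev_y[k + 3L] <- "timeout_start"; ev_c[k + 3L] <- NA
      ev_t[k + 4L] <- min(timeout_until, t_end)
      ev_y[k + 4L] <- "timeout_end"; ev_c[k + 4L] <- NA
      k <- k + 4L
      counter <- 0L
    }
  }
  k <- k + 1L
  ev_t[k] <- 0; ev_y[k] <- "period_start"; ev_c[k] <- NA
  k <- k + 1L
  ev_t[k] <- t_end; ev_y[k] <- "period_end"; ev_c[k] <- NA
  k <- k + 1L
  ev_t[k] <- t_end; ev_y[k] <- "session_end"; ev_c[k] <- NA
  new_event_log(ev_t[seq_len(k)], ev_y[seq_len(k)], ev_c[seq_len(k)],
                mouse_id, session_index, "shock", config)
}
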