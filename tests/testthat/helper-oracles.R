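# Independent brute-force oracles for the schedule state machines, written
# as naive chronological walks kept deliberately separate from the package
# implementation, plus random press-stream generators for property tests.

.oracle_rank <- function(type) {
  switch(type,
         period_end = 1, period_start = 2, timeout_end = 3,
         active_press = 4, inactive_press = 4, shock = 5,
         pellet = 6, timeout_start = 7, session_end = 8)
}

.oracle_sort <- function(ev) {
  if (!length(ev)) return(data.frame(time_s = numeric(),
                                     event_type = character(),
                                     countable = logical()))
  df <- do.call(rbind, lapply(ev, function(e)
    data.frame(time_s = e$t, event_type = e$y,
               countable = e$c, stringsAsFactors = FALSE)))
  rk <- vapply(df$event_type, .oracle_rank, 1.0)
  df[order(df$time_s, rk, seq_len(nrow(df))), , drop = FALSE]
}

# naive FR walk: one press at a time, explicit state
oracle_fr <- function(stream, cfg) {
  free_lo <- cfg$pellet_period_1_s
  free_hi <- free_lo + cfg$pellet_free_s
  session_end <- free_hi + cfg$pellet_period_2_s
  ev <- list()
  push <- function(t, y, c = NA) ev[[length(ev) + 1L]] <<- list(t = t, y = y, c = c)
  push(0, "period_start")
  if (cfg$pellet_free_s > 0) {
    push(free_lo, "period_end"); push(free_lo, "period_start")
    push(free_hi, "period_end")
    if (cfg$pellet_period_2_s > 0) {
      push(free_hi, "period_start"); push(session_end, "period_end")
    }
  } else push(free_lo, "period_end")
  push(session_end, "session_end")

  presses_needed <- cfg$fixed_ratio
  got <- 0
  blocked_until <- NULL
  for (i in seq_len(nrow(stream))) {
    t <- stream$time_s[i]
    if (t >= session_end) next  # dropped by the machine (with a warning)
    if (stream$lever[i] == "inactive") {
      push(t, "inactive_press", FALSE)
      next
    }
    counts <- TRUE
    if (cfg$pellet_free_s > 0 && t >= free_lo && t < free_hi) counts <- FALSE
    if (!is.null(blocked_until) && t < blocked_until) counts <- FALSE
    push(t, "active_press", counts)
    if (counts) {
      got <- got + 1
      if (got == presses_needed) {
        push(t, "pellet")
        push(t, "timeout_start")
        blocked_until <- t + cfg$timeout_s
        push(min(blocked_until, session_end), "timeout_end")
        got <- 0
      }
    }
  }
  .oracle_sort(ev)
}

# naive shock-session walk: FR5 blocks with shock at the 4th, shock+pellet
# at the 5th, 60-s reinitiation window, 10-s post-pellet time-out
oracle_shock <- function(stream, cfg) {
  session_end <- cfg$shock_session_duration_s
  ev <- list()
  push <- function(t, y, c = NA) ev[[length(ev) + 1L]] <<- list(t = t, y = y, c = c)
  push(0, "period_start")
  push(session_end, "period_end")
  push(session_end, "session_end")
  in_block <- 0
  fourth_at <- NULL
  blocked_until <- NULL
  for (i in seq_len(nrow(stream))) {
    t <- stream$time_s[i]
    if (t >= session_end) next
    if (stream$lever[i] == "inactive") {
      push(t, "inactive_press", FALSE)
      next
    }
    if (!is.null(blocked_until) && t < blocked_until) {
      push(t, "active_press", FALSE)
      next
    }
    push(t, "active_press", TRUE)
    if (in_block == cfg$fixed_ratio - 1 && !is.null(fourth_at) &&
        t >= fourth_at + cfg$shock_fifth_response_window_s) {
      in_block <- 0  # too slow: block starts over, shock re-armed
    }
    in_block <- in_block + 1
    if (in_block == cfg$fixed_ratio - 1) {
      push(t, "shock")
      fourth_at <- t
    } else if (in_block == cfg$fixed_ratio) {
      push(t, "shock"); push(t, "pellet"); push(t, "timeout_start")
      blocked_until <- t + cfg$timeout_s
      push(min(blocked_until, session_end), "timeout_end")
      in_block <- 0
    }
  }
  .oracle_sort(ev)
}

# cumulative-sum oracle: pellets earned from a total press budget in PR
oracle_pr_pellets <- function(n_presses, series) {
  sum(cumsum(series) <= n_presses)
}

# random press stream with ties, boundary hits and bursts
random_stream <- function(n, t_max, boundary_times = numeric()) {
  t <- runif(n, 0, t_max)
  if (n >= 4) {
    t[1:2] <- t[1]                               # exact tie
    if (length(boundary_times))
      t[3:4] <- sample(boundary_times, 2, replace = TRUE)
  }
  t <- sort(t)
  lever <- sample(c("active", "inactive"), n, replace = TRUE, prob = c(.85, .15))
  press_stream(t, lever)
}

event_cols <- function(log) {
  d <- as.data.frame(log)[, c("time_s", "event_type", "countable")]
  rownames(d) <- NULL
  d
}

event_cols_from_oracle <- function(df) {
  rownames(df) <- NULL
  df$countable <- as.logical(df$countable)
  df
}
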