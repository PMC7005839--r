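#' Latent behavioral trait profile of a virtual mouse
#'
#' The synthetic cohort generator drives each schedule state machine with
#' press streams sampled from a small set of latent traits. Rates are
#' Poisson-process intensities in presses per minute.
#'
#' @param active_rate Active-lever press rate during pellet periods
#'   (presses/min).
#' @param inactive_rate Inactive-lever press rate (presses/min).
#' @param persistence_factor Multiplier (>= 0) on `active_rate` during the
#'   pellet-free period; high values produce persistent food seeking.
#' @param motivation_cap Largest PR requirement the mouse will work through
#'   (positive); maps onto the breaking point.
#' @param shock_continue_prob Probability in `[0, 1]` of continuing to press
#'   after receiving a footshock; suppression is absorbing within the
#'   session.
#' @param acquisition_gain Per-session multiplicative learning factor on
#'   `active_rate` during FR1 (>= 1); `active_rate` is the trained rate
#'   reached by the last FR1 session.
#' @return A `trait_profile` list.
#' @export
trait_profile <- function(active_rate = 4, inactive_rate = 0.5,
                          persistence_factor = 0.5, motivation_cap = 150,
                          shock_continue_prob = 0.25,
                          acquisition_gain = 1.3) {
  stopifnot(active_rate >= 0, inactive_rate >= 0, persistence_factor >= 0,
            motivation_cap > 0,
            shock_continue_prob >= 0, shock_continue_prob <= 1,
            acquisition_gain >= 1)
  structure(list(active_rate = active_rate, inactive_rate = inactive_rate,
                 persistence_factor = persistence_factor,
                 motivation_cap = motivation_cap,
                 shock_continue_prob = shock_continue_prob,
                 acquisition_gain = acquisition_gain),
            class = "trait_profile")
}

#' Group-level trait distribution specification
#'
#' Describes the distribution from which a group's trait profiles are
#' sampled. Each positive trait (rates, persistence factor, motivation cap)
#' is lognormal with the given `(meanlog, sdlog)`; `shock_continue_prob` is
#' logit-normal with the given `(location, scale)`; `acquisition_gain` is
#' fixed. A scale of 0 gives a degenerate (all-identical) trait.
#'
#' The defaults are the control ("resilient-leaning") condition; see
#' [vulnerable_group()] for the planted vulnerable condition.
#'
#' @param label Group label.
#' @param n Number of mice (>= 1).
#' @param active_rate,inactive_rate,persistence_factor,motivation_cap
#'   Length-2 numeric `(meanlog, sdlog)` of the lognormal trait.
#' @param shock_continue_prob Length-2 numeric `(location, scale)` on the
#'   logit scale.
#' @param acquisition_gain Fixed learning factor.
#' @return A `group_spec` list.
#' @export
group_spec <- function(label, n,
                       active_rate = c(log(4), 0.4),
                       inactive_rate = c(log(0.5), 0.4),
                       persistence_factor = c(log(0.5), 0.5),
                       motivation_cap = c(log(150), 0.6),
                       shock_continue_prob = c(stats::qlogis(0.25), 0.8),
                       acquisition_gain = 1.3) {
  chk <- function(p) stopifnot(length(p) == 2L, is.numeric(p), p[2] >= 0)
  chk(active_rate); chk(inactive_rate); chk(persistence_factor)
  chk(motivation_cap); chk(shock_continue_prob)
  stopifnot(n >= 1, n == floor(n))
  structure(list(label = label, n = as.integer(n),
                 active_rate = active_rate, inactive_rate = inactive_rate,
                 persistence_factor = persistence_factor,
                 motivation_cap = motivation_cap,
                 shock_continue_prob = shock_continue_prob,
                 acquisition_gain = acquisition_gain),
            class = "group_spec")
}

#' Control and vulnerable group presets
#'
#' `control_group()` is [group_spec()] at its defaults. `vulnerable_group()`
#' shifts the traits that feed the three addiction-like criteria upward:
#' persistence factor x2.5, motivation cap x4, and shock-continuation
#' probability centered at 0.75 instead of 0.25 — the synthetic analogue of
#' a vulnerable phenotype.
#'
#' @param n Number of mice.
#' @param label Group label.
#' @return A `group_spec`.
#' @export
control_group <- function(n, label = "control") group_spec(label, n)

#' @rdname control_group
#' @export
vulnerable_group <- function(n, label = "vulnerable") {
  group_spec(label, n,
             persistence_factor = c(log(0.5 * 2.5), 0.5),
             motivation_cap = c(log(150 * 4), 0.6),
             shock_continue_prob = c(stats::qlogis(0.75), 0.8))
}

#' Sample a cohort of trait profiles
#'
#' @param spec A [group_spec()].
#' @param seed Optional integer seed for reproducibility.
#' @return A list of `n` [trait_profile()] objects.
#' @export
sample_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "group_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n
  rln <- function(p) stats::rlnorm(n, p[1], p[2])
  ar <- rln(spec$active_rate)
  ir <- rln(spec$inactive_rate)
  pf <- rln(spec$persistence_factor)
  mc <- rln(spec$motivation_cap)
  scp <- stats::plogis(stats::rnorm(n, spec$shock_continue_prob[1],
                                    spec$shock_continue_prob[2]))
  lapply(seq_len(n), function(i) {
    trait_profile(active_rate = ar[i], inactive_rate = ir[i],
                  persistence_factor = pf[i], motivation_cap = mc[i],
                  shock_continue_prob = scp[i],
                  acquisition_gain = spec$acquisition_gain)
  })
}

# homogeneous Poisson arrivals on [t0, t1) at rate_per_min
.poisson_times <- function(rate_per_min, t0, t1) {
  len <- t1 - t0
  if (len <= 0 || rate_per_min <= 0) return(numeric())
  m <- stats::rpois(1, rate_per_min / 60 * len)
  sort(stats::runif(m, t0, t1))
}

#' Generate a press stream for one session phase
#'
#' Active presses arrive as a Poisson process at `active_rate`, scaled by
#' `persistence_factor` during the pellet-free period; inactive presses are
#' an independent Poisson process at `inactive_rate` over the whole
#' session. The shock-session interaction (absorbing suppression after a
#' shock) is handled by [simulate_shock_session()], which truncates the
#' stream at the first shock the mouse does not tolerate.
#'
#' @param traits A [trait_profile()].
#' @param config A [session_config()]; for `"fr"` the period structure is
#'   honoured, for `"shock"` the stream covers the full session at
#'   `active_rate`.
#' @param rate_mult Multiplier on `active_rate` (FR1 learning ramp).
#' @return A [press_stream()].
#' @export
generate_press_stream <- function(traits, config, rate_mult = 1) {
  stopifnot(inherits(traits, "trait_profile"),
            inherits(config, "session_config"))
  ar <- traits$active_rate * rate_mult
  if (config$session_kind == "fr") {
    f0 <- config$pellet_period_1_s
    f1 <- f0 + config$pellet_free_s
    t_end <- f1 + config$pellet_period_2_s
    act <- c(.poisson_times(ar, 0, f0),
             .poisson_times(ar * traits$persistence_factor, f0, f1),
             .poisson_times(ar, f1, t_end))
  } else if (config$session_kind == "shock") {
    t_end <- config$shock_session_duration_s
    act <- .poisson_times(ar, 0, t_end)
  } else {
    stop("use run_pr_session() with policy_motivated() for PR sessions")
  }
  ina <- .poisson_times(traits$inactive_rate, 0, t_end)
  tt <- c(act, ina)
  lv <- rep(c("active", "inactive"), c(length(act), length(ina)))
  o <- order(tt)
  press_stream(tt[o], lv[o])
}

#' Simulate one FR session for a virtual mouse
#'
#' @inheritParams generate_press_stream
#' @param mouse_id,session_index Metadata.
#' @return An `event_log`.
#' @export
simulate_fr_session <- function(traits, config, rate_mult = 1,
                                mouse_id = NA_character_,
                                session_index = NA_integer_) {
  run_fr_session(generate_press_stream(traits, config, rate_mult),
                 config, mouse_id, session_index)
}

#' Simulate the punished (shock) session for a virtual mouse
#'
#' A candidate Poisson press stream for the full session is run through the
#' shock state machine; for each shock, in order, the mouse continues with
#' probability `shock_continue_prob`. At the first shock it does not
#' tolerate, the stream is truncated at that instant (suppression is
#' absorbing for the rest of the session) and the machine is re-run on the
#' truncated stream, which leaves all earlier events unchanged.
#'
#' @inheritParams simulate_fr_session
#' @return An `event_log`.
#' @export
simulate_shock_session <- function(traits, config = session_config("shock"),
                                   mouse_id = NA_character_,
                                   session_index = NA_integer_) {
  stream <- generate_press_stream(traits, config)
  log <- run_shock_session(stream, config, mouse_id, session_index)
  shock_t <- log$time_s[log$event_type == "shock"]
  if (length(shock_t)) {
    go_on <- stats::runif(length(shock_t)) < traits$shock_continue_prob
    stop_at <- which(!go_on)
    if (length(stop_at)) {
      ts <- shock_t[stop_at[1]]
      stream <- press_stream(stream$time_s[stream$time_s <= ts],
                             stream$lever[stream$time_s <= ts])
      log <- run_shock_session(stream, config, mouse_id, session_index)
    }
  }
  log
}

#' Simulate the PR session for a virtual mouse
#'
#' Uses [policy_motivated()]: the mouse presses at its active rate until
#' the current requirement exceeds its motivation cap.
#'
#' @inheritParams simulate_fr_session
#' @param series PR requirement series.
#' @return An `event_log`.
#' @export
simulate_pr_session <- function(traits, config = session_config("pr"),
                                series = build_pr_series(),
                                mouse_id = NA_character_,
                                session_index = NA_integer_) {
  # presses the mouse is willing to emit: every requirement <= its cap
  n_press <- sum(series[series <= traits$motivation_cap])
  if (n_press == 0 || traits$active_rate <= 0) {
    return(run_pr_session(numeric(), config, series, mouse_id,
                          session_index))
  }
  gaps <- stats::rexp(n_press, traits$active_rate / 60)
  run_pr_session(cumsum(gaps), config, series, mouse_id, session_index)
}

#' Protocol configuration
#'
#' The full phenotyping sequence: `n_fr1` FR1 acquisition sessions,
#' `n_fr5` FR5 sessions, persistence scored on the `persistence_window`
#' (default: the 3 FR5 sessions immediately before PR, i.e. the last 3),
#' then one PR session and one shock session.
#'
#' @param n_fr1 Number of FR1 sessions (default 6, as in the long in-vivo
#'   protocol).
#' @param n_fr5 Number of FR5 sessions (default 112 in vivo; simulations in
#'   this package typically use a handful since criterion scores depend
#'   only on the last sessions).
#' @param persistence_window Integer vector of FR5 session indices used for
#'   the persistence score; default the last 3.
#' @param seed Integer seed; expanded into per-mouse substreams so cohorts
#'   are reproducible independent of iteration order.
#' @return A `protocol_config` list.
#' @export
protocol_config <- function(n_fr1 = 6L, n_fr5 = 112L,
                            persistence_window = NULL, seed = 1L) {
  if (is.null(persistence_window))
    persistence_window <- (n_fr5 - 2L):n_fr5
  stopifnot(n_fr1 >= 1, n_fr5 >= 3,
            all(persistence_window >= 1), all(persistence_window <= n_fr5),
            length(persistence_window) == 3L)
  structure(list(n_fr1 = as.integer(n_fr1), n_fr5 = as.integer(n_fr5),
                 persistence_window = as.integer(persistence_window),
                 seed = as.integer(seed)),
            class = "protocol_config")
}

#' Run the full phenotyping protocol on synthetic groups
#'
#' For every mouse in every group: FR1 sessions with a multiplicative
#' learning ramp (`active_rate * gain^(i - n_fr1)`, so the trained rate is
#' reached by the last FR1 session), FR5 sessions, one PR session and one
#' shock session. Per-session summaries (reinforcers, presses by lever,
#' pellet-free active presses, shocks, breaking point) are always computed;
#' full event logs are retained when `keep_logs = TRUE`.
#'
#' @param groups A list of [group_spec()] objects (or a single one).
#' @param protocol A [protocol_config()].
#' @param fr_config FR [session_config()] (long protocol by default; its
#'   `fixed_ratio` is overridden to 1 for FR1 and 5 for FR5 sessions).
#' @param keep_logs Retain all event logs (memory-heavy for large cohorts).
#' @return A `protocol_dataset` list with elements `mice` (data.frame:
#'   `mouse_id`, `group`), `sessions` (per-session summary data.frame),
#'   `logs` (named list of event-log lists, or NULL), `protocol`.
#' @export
run_protocol <- function(groups, protocol = protocol_config(),
                         fr_config = session_config("fr"),
                         keep_logs = TRUE) {
  if (inherits(groups, "group_spec")) groups <- list(groups)
  stopifnot(all(vapply(groups, inherits, TRUE, "group_spec")))
  set.seed(protocol$seed)
  n_total <- sum(vapply(groups, `[[`, 1L, "n"))
  mouse_seeds <- sample.int(.Machine$integer.max, n_total + length(groups))

  fr1_cfg <- fr_config; fr1_cfg$fixed_ratio <- 1L
  fr5_cfg <- fr_config; fr5_cfg$fixed_ratio <- 5L
  pr_cfg <- session_config("pr")
  sh_cfg <- session_config("shock")

  mice <- list(); sessions <- list(); logs <- if (keep_logs) list() else NULL
  m <- 0L
  for (g in seq_along(groups)) {
    spec <- groups[[g]]
    set.seed(mouse_seeds[n_total + g])
    cohort <- sample_cohort(spec)
    for (i in seq_len(spec$n)) {
      m <- m + 1L
      id <- sprintf("%s_%03d", spec$label, i)
      set.seed(mouse_seeds[m])
      traits <- cohort[[i]]
      mouse_logs <- list()
      rows <- list()
      sidx <- 0L
      for (s in seq_len(protocol$n_fr1)) {
        sidx <- sidx + 1L
        mult <- traits$acquisition_gain^(s - protocol$n_fr1)
        log <- simulate_fr_session(traits, fr1_cfg, mult, id, sidx)
        rows[[length(rows) + 1L]] <- .session_summary(log, id, sidx, "fr1")
        if (keep_logs) mouse_logs[[length(mouse_logs) + 1L]] <- log
      }
      for (s in seq_len(protocol$n_fr5)) {
        sidx <- sidx + 1L
        log <- simulate_fr_session(traits, fr5_cfg, 1, id, sidx)
        rows[[length(rows) + 1L]] <- .session_summary(log, id, sidx, "fr5")
        if (keep_logs) mouse_logs[[length(mouse_logs) + 1L]] <- log
      }
      sidx <- sidx + 1L
      log <- simulate_pr_session(traits, pr_cfg, mouse_id = id,
                                 session_index = sidx)
      rows[[length(rows) + 1L]] <- .session_summary(log, id, sidx, "pr")
      if (keep_logs) mouse_logs[[length(mouse_logs) + 1L]] <- log
      sidx <- sidx + 1L
      log <- simulate_shock_session(traits, sh_cfg, id, sidx)
      rows[[length(rows) + 1L]] <- .session_summary(log, id, sidx, "shock")
      if (keep_logs) mouse_logs[[length(mouse_logs) + 1L]] <- log

      mice[[m]] <- data.frame(mouse_id = id, group = spec$label,
                              stringsAsFactors = FALSE)
      sessions[[m]] <- do.call(rbind, rows)
      if (keep_logs) logs[[id]] <- mouse_logs
    }
  }
  structure(list(mice = do.call(rbind, mice),
                 sessions = do.call(rbind, sessions),
                 logs = logs, protocol = protocol),
            class = "protocol_dataset")
}

.session_summary <- function(log, id, sidx, phase) {
  data.frame(
    mouse_id = id, session_index = sidx, phase = phase,
    reinforcers = count_reinforcers(log),
    active_presses = count_presses(log, "active"),
    inactive_presses = count_presses(log, "inactive"),
    pellet_free_active = count_pellet_free_active(log),
    shocks = count_shocks(log),
    breaking_point = if (phase == "pr")
      breaking_point(count_reinforcers(log)) else NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' @export
print.protocol_dataset <- function(x, ...) {
  cat("<protocol_dataset>", nrow(x$mice), "mice,",
      nrow(x$sessions), "sessions",
      if (is.null(x$logs)) "(summaries only)" else "(logs retained)", "\n")
  invisible(x)
}

#' Idealized continuous control criterion scores
#'
#' Draws per-mouse criterion scores directly from continuous, mutually
#' independent distributions (lognormal for each of persistence,
#' motivation and compulsivity), representing the idealized control
#' population in which the percentile-attribution calibration is exact:
#' with continuous independent scores, the probability of flagging at or
#' above 2 of 3 criteria at their own 75th percentiles is
#' 3(0.25^2)(0.75) + 0.25^3 = 0.15625. Event-level scores are discrete
#' (the breaking point lives on the PR series, shocks are small integers),
#' so ties make this identity approximate there; this generator exists to
#' separate classifier calibration from score discreteness. An optional
#' Gaussian-copula `correlation` couples the three scores, since real
#' criteria correlate.
#'
#' @param n Number of mice.
#' @param correlation Common pairwise latent correlation in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return A data.frame with `mouse_id`, `persistence`, `motivation`,
#'   `compulsivity`.
#' @export
simulate_control_scores <- function(n, correlation = 0, seed = NULL) {
  stopifnot(n >= 1, correlation >= 0, correlation < 1)
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(stats::rnorm(3 * n), n, 3)
  if (correlation > 0) {
    shared <- stats::rnorm(n)
    z <- sqrt(correlation) * shared + sqrt(1 - correlation) * z
  }
  data.frame(
    mouse_id = sprintf("m%04d", seq_len(n)),
    persistence = exp(log(20) + 0.6 * z[, 1]),
    motivation = exp(log(150) + 0.6 * z[, 2]),
    compulsivity = exp(log(5) + 0.6 * z[, 3]),
    stringsAsFactors = FALSE
  )
}
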