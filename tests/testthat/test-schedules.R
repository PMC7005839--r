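single_period_cfg <- function(len = 60, fr = 5)
  session_config("fr", fixed_ratio = fr, pellet_period_1_s = len,
                 pellet_free_s = 0, pellet_period_2_s = 0)

test_that("FR5 worked example: one press per second earns pellets at 4 and 18", {
  log <- run_fr_session(press_stream(0:29), single_period_cfg())
  expect_equal(count_reinforcers(log), 2)
  expect_equal(log$time_s[log$event_type == "pellet"], c(4, 18))
  expect_identical(event_cols(log),
                   event_cols_from_oracle(oracle_fr(press_stream(0:29),
                                                    single_period_cfg())))
  validate_event_log(log)
})

test_that("empty stream yields only session markers and no pellets", {
  log <- run_fr_session(press_stream(), session_config("fr"))
  expect_equal(count_reinforcers(log), 0)
  expect_true(all(log$event_type %in%
                    c("period_start", "period_end", "session_end")))
})

test_that("no pellet is delivered for presses in the pellet-free period", {
  cfg <- session_config("fr", fixed_ratio = 5)
  t0 <- cfg$pellet_period_1_s
  log <- run_fr_session(press_stream(t0 + c(10, 20, 30, 40, 50)), cfg)
  expect_equal(count_reinforcers(log), 0)
  presses <- log[log$event_type == "active_press", ]
  expect_equal(nrow(presses), 5)
  expect_false(any(presses$countable))
  expect_equal(count_pellet_free_active(log), 5)
})

test_that("presses at or beyond session end are dropped with a warning", {
  cfg <- single_period_cfg(60)
  expect_warning(log <- run_fr_session(press_stream(c(1, 2, 59, 60, 61)), cfg),
                 "dropped")
  expect_equal(count_presses(log, "active"), 3)
})

test_that("the ratio counter persists across the pellet-free period", {
  cfg <- session_config("fr", fixed_ratio = 5, pellet_period_1_s = 60,
                        pellet_free_s = 60, pellet_period_2_s = 60)
  # 3 countable presses before the free period, 2 after: pellet on the 5th
  log <- run_fr_session(press_stream(c(1, 2, 3, 70, 125, 130)), cfg)
  expect_equal(count_reinforcers(log), 1)
  expect_equal(log$time_s[log$event_type == "pellet"], 130)
})

test_that("PR session: cumulative-sum oracle, inactivity end and 5-h cap", {
  cfg <- session_config("pr")
  log <- run_pr_session(policy_fixed_presses(18), cfg)
  expect_equal(count_reinforcers(log), 3)   # requirements 1 + 5 + 12
  expect_equal(breaking_point(log), 12)
  # ends by inactivity one hour after the last press (t = 18 at 1 press/s)
  expect_equal(max(log$time_s), 18 + cfg$pr_inactivity_limit_s)

  silent <- run_pr_session(policy_fixed_presses(0), cfg)
  expect_equal(count_reinforcers(silent), 0)
  expect_equal(breaking_point(silent), 0)
  expect_equal(max(silent$time_s), cfg$pr_inactivity_limit_s)

  endless <- run_pr_session(policy_unbounded(rate_per_min = 120), cfg)
  expect_equal(max(endless$time_s), cfg$pr_max_duration_s)
  # presses at 2/s for 5 h: the oracle says how many ratios were completed
  n_presses <- count_presses(endless, "active")
  expect_equal(count_reinforcers(endless),
               oracle_pr_pellets(n_presses, build_pr_series()))
})

test_that("PR pellet count matches the cumulative-sum oracle for any budget", {
  cfg <- session_config("pr")
  for (n in c(1, 5, 6, 17, 19, 250)) {
    log <- run_pr_session(policy_fixed_presses(n, rate_per_min = 600), cfg)
    expect_equal(count_reinforcers(log),
                 oracle_pr_pellets(n, build_pr_series()))
  }
})

test_that("PR vector path and callback path produce identical logs", {
  cfg <- session_config("pr")
  replay <- function(v) {
    i <- 0L
    prev <- 0
    function(ctx) {
      i <<- i + 1L
      if (i > length(v)) return(Inf)
      dt <- v[i] - prev
      prev <<- v[i]
      dt
    }
  }
  set.seed(77)
  cases <- list(
    cumsum(rexp(120, 1 / 2)),                 # plain pressing
    cumsum(rexp(30, 1 / 2)),                  # quits early -> inactivity end
    cumsum(rexp(60000, 2)),                   # dense -> series exhaustion
    seq(100, 30000, by = 100),                # sparse but under the 1-h gap
    c(10, 20, 20 + 3600 + 1, 7300),           # inactivity gap mid-stream
    cumsum(rexp(25000, 0.8)),                 # runs into the 5-h cap
    numeric()                                 # never presses
  )
  for (v in cases) {
    a <- run_pr_session(v, cfg)
    b <- run_pr_session(replay(v), cfg)
    expect_identical(event_cols(a), event_cols(b))
  }
})

test_that("shock session: 4th press shocks without pellet, 5th shocks with", {
  cfg <- session_config("shock")
  log <- run_shock_session(press_stream(c(0, 1, 2, 3)), cfg)
  expect_equal(count_shocks(log), 1)
  expect_equal(count_reinforcers(log), 0)

  log5 <- run_shock_session(press_stream(c(0, 1, 2, 3, 4)), cfg)
  expect_equal(count_shocks(log5), 2)
  expect_equal(count_reinforcers(log5), 1)

  empty <- run_shock_session(press_stream(), cfg)
  expect_equal(count_shocks(empty), 0)
  expect_equal(count_reinforcers(empty), 0)
})

test_that("dense pressing gives two shocks per completed block", {
  cfg <- session_config("shock")
  log <- run_shock_session(press_stream(seq(0, 2998, by = 2)), cfg)
  expect_equal(count_shocks(log), 2 * count_reinforcers(log))
  expect_identical(event_cols(log),
                   event_cols_from_oracle(
                     oracle_shock(press_stream(seq(0, 2998, by = 2)), cfg)))
})

test_that("block reinitiates when the 5th response is slower than 60 s", {
  cfg <- session_config("shock")
  # 4 quick presses (shock), then a press 61 s later: new block press 1,
  # and the next 4 quick presses re-reach the shock
  log <- run_shock_session(press_stream(c(0, 1, 2, 3, 64, 65, 66, 67)), cfg)
  expect_equal(count_shocks(log), 2)
  expect_equal(count_reinforcers(log), 0)
  # 5th press inside the window completes the block instead
  log2 <- run_shock_session(press_stream(c(0, 1, 2, 3, 62.9)), cfg)
  expect_equal(count_shocks(log2), 2)
  expect_equal(count_reinforcers(log2), 1)
})

test_that("FR machine matches the chronological event-walk oracle on random streams", {
  set.seed(101)
  cfgs <- list(session_config("fr", fixed_ratio = 5),
               session_config("fr", fixed_ratio = 1),
               single_period_cfg(120, 3),
               session_config("fr", fixed_ratio = 5, protocol = "short"))
  for (rep in 1:60) {
    cfg <- cfgs[[1 + rep %% length(cfgs)]]
    t_end <- cfg$pellet_period_1_s + cfg$pellet_free_s + cfg$pellet_period_2_s
    bounds <- c(cfg$pellet_period_1_s,
                cfg$pellet_period_1_s + cfg$pellet_free_s)
    st <- random_stream(sample(0:80, 1), t_end * 1.02, bounds)
    got <- suppressWarnings(run_fr_session(st, cfg))
    expect_identical(event_cols(got), event_cols_from_oracle(oracle_fr(st, cfg)))
    validate_event_log(got)
  }
})

test_that("shock machine matches the event-walk oracle on random streams", {
  set.seed(202)
  cfg <- session_config("shock")
  for (rep in 1:60) {
    st <- random_stream(sample(0:120, 1), cfg$shock_session_duration_s * 1.02)
    got <- suppressWarnings(run_shock_session(st, cfg))
    expect_identical(event_cols(got), event_cols_from_oracle(oracle_shock(st, cfg)))
  }
})

test_that("pellet bookkeeping invariants hold on random FR logs", {
  set.seed(303)
  cfg <- session_config("fr", fixed_ratio = 5)
  t_end <- cfg$pellet_period_1_s + cfg$pellet_free_s + cfg$pellet_period_2_s
  for (rep in 1:20) {
    st <- random_stream(150, t_end)
    log <- run_fr_session(st, cfg)
    pellets <- count_reinforcers(log)
    countable <- sum(log$event_type == "active_press" & log$countable %in% TRUE)
    expect_lte(pellets, countable / cfg$fixed_ratio)
    # pellets never in the pellet-free period
    pel_t <- log$time_s[log$event_type == "pellet"]
    expect_false(any(pel_t >= cfg$pellet_period_1_s &
                       pel_t < cfg$pellet_period_1_s + cfg$pellet_free_s))
  }
})

test_that("shock counts bound pellet counts on random shock logs", {
  set.seed(404)
  cfg <- session_config("shock")
  for (rep in 1:20) {
    st <- random_stream(200, cfg$shock_session_duration_s)
    log <- run_shock_session(st, cfg)
    shocks <- count_shocks(log)
    pellets <- count_reinforcers(log)
    expect_gte(shocks, pellets)
    # every completed block carries exactly two shocks; extra shocks are
    # lone 4th-press shocks, each consuming at least 4 countable presses
    expect_gte(shocks, 2 * pellets)
    countable <- sum(log$event_type == "active_press" & log$countable %in% TRUE)
    expect_lte(shocks, 2 * pellets + (countable - 5 * pellets) / 4)
  }
})
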