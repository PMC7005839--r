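# builds a minimal mouse log set: 3 FR5 sessions with chosen pellet-free
# press counts, one PR log with a given breaking point, one shock log
make_mouse_logs <- function(pf_counts = c(10, 20, 30), pr_presses = 18,
                            shock_presses = c(0, 1, 2, 3)) {
  cfg <- session_config("fr", fixed_ratio = 5)
  f0 <- cfg$pellet_period_1_s
  frs <- lapply(seq_along(pf_counts), function(i) {
    k <- pf_counts[i]
    t <- if (k > 0) f0 + seq(1, by = 2, length.out = k) else numeric()
    run_fr_session(press_stream(t), cfg, "m1", i)
  })
  pr <- run_pr_session(policy_fixed_presses(pr_presses),
                       session_config("pr"), mouse_id = "m1",
                       session_index = length(pf_counts) + 1L)
  sh <- run_shock_session(press_stream(shock_presses),
                          session_config("shock"), "m1",
                          length(pf_counts) + 2L)
  c(frs, list(pr), list(sh))
}

test_that("criterion scoring: persistence mean, breaking point, shock count", {
  logs <- make_mouse_logs(pf_counts = c(10, 20, 30), pr_presses = 18,
                          shock_presses = c(0, 1, 2, 3))
  sc <- score_criteria(logs)
  expect_equal(sc$persistence, 20)   # mean of 10, 20, 30
  expect_equal(sc$motivation, 12)    # 18 presses complete 1 + 5 + 12
  expect_equal(sc$compulsivity, 1)   # 4 presses: one shock

  zero_pr <- make_mouse_logs(pr_presses = 0)
  expect_equal(score_criteria(zero_pr)$motivation, 0)

  dense <- make_mouse_logs(shock_presses = seq(0, 20, by = 2))
  expect_equal(score_criteria(dense)$compulsivity,
               count_shocks(dense[[5]]))
})

test_that("missing sessions are reported by the name of the missing test", {
  logs <- make_mouse_logs()
  expect_error(score_criteria(logs[-4]), "motivation")
  expect_error(score_criteria(logs[-5]), "compulsivity")
  expect_error(score_criteria(logs[4:5]), "persistence")
})

test_that("acquisition criteria: stability, lever discrimination, minimum pellets", {
  expect_true(check_acquisition(c(10, 10, 10)))
  expect_false(check_acquisition(c(10, 10, 4)))   # < 5 reinforcers once
  expect_false(check_acquisition(c(5, 10, 15)))   # 50% deviation from mean
  expect_false(check_acquisition(c(10, 10, 10), active_fraction = 0.5))
  expect_true(check_acquisition(c(9, 10, 11)))    # 10% deviation
  # any qualifying triple suffices
  expect_true(check_acquisition(c(0, 0, 0, 8, 9, 10)))
  expect_error(check_acquisition(c(5, 6)), "3 sessions")
})

test_that("exclusion requires both low responding and failed acquisition", {
  fr5 <- function(id, reinf, act = 100, inact = 0)
    data.frame(mouse_id = id, phase = "fr5", reinforcers = reinf,
               active_presses = act, inactive_presses = inact,
               stringsAsFactors = FALSE)
  ss <- rbind(
    fr5("always", c(10, 10, 10, 10)),
    fr5("never", c(0, 0, 0, 0)),
    # responds in exactly 25% of sessions (not < 25%): kept outright
    fr5("borderline", c(1, 0, 0, 0)),
    # responds in 3/13 sessions (< 25%) but acquires in one triple: the
    # exclusion conjunction fails, so the mouse is kept
    fr5("acquirer", c(8, 9, 10, rep(0, 10))))
  res <- apply_exclusion(ss)
  res <- res[match(c("always", "never", "borderline", "acquirer"),
                   res$mouse_id), ]
  expect_equal(res$excluded, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(res$responded_fraction,
               c(1, 0, 0.25, 3 / 13))
  expect_true(res$acquired[4])
})

test_that("control 75th percentile uses linear interpolation", {
  same <- data.frame(persistence = rep(3, 6), motivation = rep(3, 6),
                     compulsivity = rep(3, 6))
  expect_equal(unname(compute_thresholds(same)), c(3, 3, 3))
  quart <- data.frame(persistence = 1:4, motivation = c(2, 4, 6, 8),
                      compulsivity = c(0, 0, 10, 10))
  thr <- compute_thresholds(quart)
  expect_equal(unname(thr["persistence"]), 3.25)
  expect_equal(unname(thr["motivation"]), 6.5)
  expect_error(compute_thresholds(quart[0, ]), "empty")
})

test_that("2-of-3 classification with at-or-above threshold comparison", {
  thr <- c(persistence = 10, motivation = 100, compulsivity = 5)
  sc <- data.frame(
    persistence = c(10, 9, 20, 9),
    motivation = c(100, 200, 50, 99),
    compulsivity = c(4, 4, 9, 4))
  att <- attribute_and_classify(sc, thr)
  expect_equal(att$n_criteria, c(2, 1, 2, 0))
  expect_equal(att$label, c("addicted", "non_addicted", "addicted",
                            "non_addicted"))
  # strict mode drops the exact-threshold flags
  att_strict <- attribute_and_classify(sc, thr, strict = TRUE)
  expect_equal(att_strict$n_criteria, c(0, 1, 2, 0))
})

test_that("classification is invariant under joint monotone transforms", {
  set.seed(21)
  sc <- simulate_control_scores(120)
  sc$group <- rep(c("control", "test"), each = 60)
  base <- classify_cohort(sc, control = "control")
  tr <- sc
  tr$persistence <- log1p(tr$persistence)   # strictly increasing
  tr$motivation <- tr$motivation^3
  tr$compulsivity <- exp(tr$compulsivity / max(tr$compulsivity))
  trans <- classify_cohort(tr, control = "control")
  expect_identical(base$attribution$label, trans$attribution$label)
  expect_identical(base$attribution$n_criteria, trans$attribution$n_criteria)
})

test_that("each criterion flags about a quarter of the control group itself", {
  set.seed(31)
  sc <- simulate_control_scores(400)
  sc$group <- "control"
  cl <- classify_cohort(sc, control = "control")
  att <- cl$attribution
  for (fl in c("flag_persistence", "flag_motivation", "flag_compulsivity")) {
    frac <- mean(att[[fl]])
    expect_gte(frac, 0.20)
    expect_lte(frac, 0.30)
  }
})

test_that("thresholds come from the control group only", {
  set.seed(41)
  sc <- simulate_control_scores(200)
  sc$group <- rep(c("control", "test"), each = 100)
  # inflating the test group must not move the thresholds
  inflated <- sc
  idx <- inflated$group == "test"
  inflated$persistence[idx] <- inflated$persistence[idx] * 100
  expect_identical(classify_cohort(sc, control = "control")$thresholds,
                   classify_cohort(inflated, control = "control")$thresholds)
})
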