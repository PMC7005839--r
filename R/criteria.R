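#' Score the three addiction-like criteria for one mouse
#'
#' Persistence to response: mean number of non-reinforced active presses
#' during the 10-min pellet-free period over the 3 FR5 sessions preceding
#' the PR test. Motivation: the PR breaking point. Compulsivity: total
#' shocks in the punished session.
#'
#' @param logs A list of `event_log`s for one mouse containing (at least)
#'   3 FR5 sessions in the persistence window, one PR log and one shock
#'   log.
#' @param window Session indices (into `logs`, by their `session_index`
#'   metadata) of the 3 pre-PR FR5 sessions; by default the last 3 FR
#'   sessions present.
#' @return A one-row data.frame: `persistence`, `motivation`,
#'   `compulsivity`.
#' @export
score_criteria <- function(logs, window = NULL) {
  kinds <- vapply(logs, function(l) l$session_kind[1], "")
  pr <- which(kinds == "pr")
  sh <- which(kinds == "shock")
  fr <- which(kinds == "fr")
  if (!length(pr)) stop("missing motivation test (no PR session log)")
  if (!length(sh)) stop("missing compulsivity test (no shock session log)")
  if (length(fr) < 3) stop("missing persistence test (need 3 pre-PR FR sessions)")
  if (is.null(window)) {
    window <- utils::tail(fr, 3)
  } else {
    sidx <- vapply(logs, function(l) l$session_index[1], 1L)
    window <- match(window, sidx)
    if (anyNA(window)) stop("persistence window sessions not found in logs")
  }
  stopifnot(length(window) == 3L)
  pf <- vapply(logs[window], count_pellet_free_active, 1L)
  data.frame(
    persistence = mean(pf),
    motivation = breaking_point(logs[[pr[length(pr)]]]),
    compulsivity = count_shocks(logs[[sh[length(sh)]]])
  )
}

#' Criterion scores for every mouse in a protocol dataset
#'
#' Vectorized scoring from the per-session summaries of
#' [run_protocol()]: persistence over the protocol's persistence window,
#' motivation from the PR session, compulsivity from the shock session.
#'
#' @param dataset A `protocol_dataset`.
#' @return A data.frame: `mouse_id`, `group`, `persistence`, `motivation`,
#'   `compulsivity`.
#' @export
criterion_scores <- function(dataset) {
  stopifnot(inherits(dataset, "protocol_dataset"))
  ss <- dataset$sessions
  win <- dataset$protocol$persistence_window
  out <- lapply(seq_len(nrow(dataset$mice)), function(i) {
    id <- dataset$mice$mouse_id[i]
    s <- ss[ss$mouse_id == id, ]
    fr5 <- s[s$phase == "fr5", ]
    data.frame(
      mouse_id = id, group = dataset$mice$group[i],
      persistence = mean(fr5$pellet_free_active[win]),
      motivation = s$breaking_point[s$phase == "pr"][1],
      compulsivity = s$shocks[s$phase == "shock"][1],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Operant acquisition check
#'
#' TRUE iff some 3 consecutive sessions simultaneously satisfy: (1) stable
#' responding, every session's reinforcer count deviating < 20% from the
#' mean of the triple; (2) at least 75% of presses on the active lever in
#' each session; (3) at least 5 reinforcers in each session. A session
#' with no presses fails the lever-discrimination condition.
#'
#' @param reinforcers Integer vector of per-session reinforcer counts.
#' @param active_fraction Per-session fraction of presses on the active
#'   lever (default 1, i.e. perfect discrimination).
#' @return Logical flag.
#' @examples
#' check_acquisition(c(10, 10, 10))          # TRUE
#' check_acquisition(c(10, 10, 4))           # FALSE (min 5 reinforcers)
#' check_acquisition(c(5, 10, 15))           # FALSE (50% deviation)
#' @export
check_acquisition <- function(reinforcers, active_fraction = 1) {
  n <- length(reinforcers)
  if (n < 3) stop("acquisition check needs at least 3 sessions")
  active_fraction <- rep_len(active_fraction, n)
  for (i in seq_len(n - 2L)) {
    r <- reinforcers[i:(i + 2L)]
    af <- active_fraction[i:(i + 2L)]
    m <- mean(r)
    if (m == 0) next
    stable <- all(abs(r - m) / m < 0.20)
    lever_ok <- all(!is.na(af) & af >= 0.75)
    enough <- all(r >= 5)
    if (stable && lever_ok && enough) return(TRUE)
  }
  FALSE
}

#' Exclusion rule over the FR5 history
#'
#' A mouse is excluded iff it responded (earned at least one reinforcer)
#' in fewer than 25% of all FR5 sessions AND never met the acquisition
#' criteria — the conjunction of the two conditions.
#'
#' @param dataset A `protocol_dataset`, or a data.frame of FR5 session
#'   summaries with columns `mouse_id`, `reinforcers`, `active_presses`,
#'   `inactive_presses`.
#' @return A data.frame `mouse_id`, `responded_fraction`, `acquired`,
#'   `excluded`.
#' @export
apply_exclusion <- function(dataset) {
  ss <- if (inherits(dataset, "protocol_dataset")) {
    dataset$sessions[dataset$sessions$phase == "fr5", ]
  } else dataset
  out <- lapply(split(ss, ss$mouse_id), function(s) {
    total <- s$active_presses + s$inactive_presses
    af <- ifelse(total > 0, s$active_presses / total, NA_real_)
    resp <- mean(s$reinforcers >= 1)
    acq <- check_acquisition(s$reinforcers, af)
    data.frame(mouse_id = s$mouse_id[1], responded_fraction = resp,
               acquired = acq, excluded = resp < 0.25 && !acq,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Control 75th-percentile criterion thresholds
#'
#' Per-criterion threshold = the 75th percentile of the control group's
#' empirical score distribution, computed with the linear-interpolation
#' quantile convention (`stats::quantile` type 7): for control scores
#' `{1, 2, 3, 4}` the threshold is 3.25.
#'
#' @param control_scores A data.frame with columns `persistence`,
#'   `motivation`, `compulsivity` for the control group (after exclusion).
#' @param probs Percentile (default 0.75).
#' @return A named numeric vector of three thresholds.
#' @export
compute_thresholds <- function(control_scores, probs = 0.75) {
  cols <- c("persistence", "motivation", "compulsivity")
  stopifnot(all(cols %in% names(control_scores)))
  if (nrow(control_scores) == 0) stop("control group is empty")
  vapply(control_scores[cols],
         function(x) unname(stats::quantile(x, probs, type = 7)), 1.0)
}

#' Attribute criteria and classify mice
#'
#' A mouse is positive for a criterion when its score is equal to or
#' beyond the control 75th percentile (`>=`; set `strict = TRUE` for a
#' strictly-above comparison). Mice with 2 or 3 positive criteria are
#' classified addicted; 0 or 1, non-addicted.
#'
#' @param scores Data.frame with columns `persistence`, `motivation`,
#'   `compulsivity` (and optionally `mouse_id`, `group`).
#' @param thresholds Named vector from [compute_thresholds()].
#' @param strict Use `>` instead of the default `>=`.
#' @return The input data.frame augmented with `flag_persistence`,
#'   `flag_motivation`, `flag_compulsivity`, `n_criteria`, `label`.
#' @export
attribute_and_classify <- function(scores, thresholds, strict = FALSE) {
  cols <- c("persistence", "motivation", "compulsivity")
  stopifnot(all(cols %in% names(scores)),
            all(cols %in% names(thresholds)))
  cmp <- if (strict) `>` else `>=`
  out <- scores
  for (cl in cols) out[[paste0("flag_", cl)]] <- cmp(scores[[cl]], thresholds[[cl]])
  out$n_criteria <- out$flag_persistence + out$flag_motivation +
    out$flag_compulsivity
  out$label <- ifelse(out$n_criteria >= 2, "addicted", "non_addicted")
  out
}

#' Phenotype a simulated or recorded cohort end to end
#'
#' Applies the exclusion rule, computes criterion thresholds on the kept
#' control-group mice, and attributes/classifies every kept mouse.
#'
#' @param scores Per-mouse criterion scores with `mouse_id`, `group`
#'   columns (e.g. from [criterion_scores()]).
#' @param exclusion Optional data.frame from [apply_exclusion()].
#' @param control Label of the control group (threshold source).
#' @param strict Comparison mode, see [attribute_and_classify()].
#' @return A list: `attribution` (per-mouse data.frame, with `excluded`
#'   column), `thresholds`, `group_summary` (per-group n, n_addicted,
#'   addicted fraction).
#' @export
classify_cohort <- function(scores, exclusion = NULL, control = "control",
                            strict = FALSE) {
  stopifnot(all(c("mouse_id", "group") %in% names(scores)))
  if (!is.null(exclusion)) {
    scores$excluded <- exclusion$excluded[match(scores$mouse_id,
                                                exclusion$mouse_id)]
  } else scores$excluded <- FALSE
  kept <- scores[!scores$excluded, ]
  ctrl <- kept[kept$group == control, ]
  if (nrow(ctrl) == 0) stop("no control-group mice after exclusion")
  thr <- compute_thresholds(ctrl)
  att <- attribute_and_classify(kept, thr, strict = strict)
  gs <- do.call(rbind, lapply(split(att, att$group), function(g) {
    data.frame(group = g$group[1], n = nrow(g),
               n_addicted = sum(g$label == "addicted"),
               addicted_fraction = mean(g$label == "addicted"),
               stringsAsFactors = FALSE)
  }))
  rownames(gs) <- NULL
  list(attribution = att, thresholds = thr, group_summary = gs)
}
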