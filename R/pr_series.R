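#' Progressive-ratio escalation series
#'
#' Returns the 35-step response-requirement series used in the
#' progressive-ratio (PR) session: the number of active lever presses
#' required to earn each successive pellet. The series starts at 1 and
#' ends at 5500; the last requirement an animal completes is its
#' breaking point.
#'
#' @return Integer vector of length 35, strictly increasing from 1 to 5500.
#' @examples
#' s <- build_pr_series()
#' s[1]; s[35]
#' @export
build_pr_series <- function() {
  c(1L, 5L, 12L, 21L, 33L, 51L, 75L, 90L, 120L, 155L,
    180L, 225L, 260L, 300L, 350L, 410L, 465L, 540L, 630L, 730L,
    850L, 1000L, 1200L, 1500L, 1800L, 2100L, 2400L, 2700L, 3000L,
    3400L, 3800L, 4200L, 4600L, 5000L, 5500L)
}

#' Breaking point from completed ratios
#'
#' The breaking point is the last response requirement the animal
#' completed in the PR session. With zero completed requirements the
#' breaking point is defined as 0.
#'
#' @param x An `event_log` from [run_pr_session()] (pellets are counted),
#'   or a single non-negative integer giving the number of completed ratios.
#' @param series The PR requirement series, by default [build_pr_series()].
#' @return A single number: 0, or the requirement of the last completed ratio.
#' @export
breaking_point <- function(x, series = build_pr_series()) {
  n <- if (inherits(x, "event_log")) count_reinforcers(x) else x
  stopifnot(length(n) == 1L, is.numeric(n), n >= 0, n == floor(n))
  if (n > length(series)) {
    stop("number of completed ratios (", n, ") exceeds the series length (",
         length(series), ")")
  }
  if (n == 0) 0L else series[[n]]
}
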