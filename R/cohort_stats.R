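#' Mann-Whitney U comparison of two groups
#'
#' Two-group comparison of criterion scores. Reports U = min(U1, U2)
#' (the convention used when reading published U values) and the
#' two-sided p-value: exact for small samples without ties, normal
#' approximation with tie correction otherwise (via
#' [stats::wilcox.test()]).
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"` (default), `"less"`, `"greater"`.
#' @return A `group_comparison` list: `test`, `statistic`, `p_value`,
#'   `n`, `direction`, `stars`.
#' @export
mann_whitney <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) >= 1, length(y) >= 1)
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = NULL))
  u1 <- unname(wt$statistic)          # wilcox.test's W is U for x over y
  u <- min(u1, length(x) * length(y) - u1)
  .group_comparison("mann_whitney", u, wt$p.value,
                    c(length(x), length(y)),
                    direction = if (stats::median(x) >= stats::median(y))
                      "x>=y" else "x<y")
}

#' Chi-square goodness of fit against control frequencies
#'
#' Compares the observed addicted/non-addicted counts of a test group with
#' the frequencies expected under the control group's addicted proportion:
#' a 1-df goodness-of-fit chi-square on expected counts
#' `n * (p, 1 - p)`.
#'
#' @param labels Character vector of test-group labels
#'   (`"addicted"`/`"non_addicted"`), or a length-2 count vector
#'   `c(addicted, non_addicted)`.
#' @param control_prop Control addicted proportion, strictly in (0, 1).
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @return A `group_comparison`.
#' @export
chi_square_vs_control <- function(labels, control_prop, correct = FALSE) {
  stopifnot(control_prop > 0, control_prop < 1)
  obs <- if (is.numeric(labels) && length(labels) == 2L) labels
  else c(sum(labels == "addicted"), sum(labels != "addicted"))
  n <- sum(obs)
  stopifnot(n >= 1)
  expd <- n * c(control_prop, 1 - control_prop)
  if (correct) {
    stat <- sum((abs(obs - expd) - 0.5)^2 / expd)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    ct <- suppressWarnings(
      stats::chisq.test(obs, p = c(control_prop, 1 - control_prop),
                        correct = FALSE))
    stat <- unname(ct$statistic)
    p <- ct$p.value
  }
  .group_comparison("chi_square_gof", stat, p, n,
                    direction = if (obs[1] / n >= control_prop)
                      "above_control" else "below_control")
}

#' Pearson correlation between criterion values and criteria achieved
#'
#' @param x,y Numeric vectors of equal length (n >= 3), e.g. a criterion's
#'   scores and the number of criteria achieved.
#' @return A `group_comparison` with `statistic` = r and the p-value from
#'   the t transform.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the vectors")
  ct <- stats::cor.test(x, y, method = "pearson")
  .group_comparison("pearson", unname(ct$estimate), ct$p.value, length(x),
                    direction = if (ct$estimate >= 0) "positive" else "negative")
}

.group_comparison <- function(test, statistic, p, n, direction) {
  structure(list(test = test, statistic = statistic, p_value = p,
                 n = n, direction = direction,
                 stars = significance_stars(p)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g %s (n = %s)\n",
              x$test, x$statistic, x$p_value, x$stars,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Significance stars
#'
#' Figure-legend mapping: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' `ns` otherwise.
#'
#' @param p P-value(s).
#' @return Character vector of stars.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Group statistics for an attribution result
#'
#' Runs the statistical layer over a classified cohort: per-criterion
#' Mann-Whitney tests between each test group and the control group,
#' chi-square of each test group's addicted frequency against the control
#' proportion, and Pearson correlations between each criterion's values
#' and the number of criteria achieved (per group). Bonferroni correction
#' across the Mann-Whitney family is available but off by default, since
#' uncorrected per-test comparisons are the norm in this design.
#'
#' @param classified Result of [classify_cohort()].
#' @param control Control group label.
#' @param bonferroni Multiply Mann-Whitney p-values by the number of
#'   tests.
#' @return A nested list of `group_comparison` objects, suitable for
#'   [write_group_summary()].
#' @export
cohort_statistics <- function(classified, control = "control",
                              bonferroni = FALSE) {
  att <- classified$attribution
  ctrl <- att[att$group == control, ]
  tests <- setdiff(unique(att$group), control)
  crit <- c("persistence", "motivation", "compulsivity")
  out <- list(thresholds = as.list(classified$thresholds),
              group_summary = classified$group_summary)
  mw <- list()
  for (g in tests) {
    tg <- att[att$group == g, ]
    for (cl in crit) {
      cmp <- mann_whitney(tg[[cl]], ctrl[[cl]])
      mw[[paste(g, cl, sep = ".")]] <- cmp
    }
    p0 <- mean(ctrl$label == "addicted")
    out$chi_square[[g]] <- if (p0 > 0 && p0 < 1)
      chi_square_vs_control(tg$label, p0) else NULL
  }
  if (bonferroni) {
    for (nm in names(mw)) {
      mw[[nm]]$p_value <- min(1, mw[[nm]]$p_value * length(mw))
      mw[[nm]]$stars <- significance_stars(mw[[nm]]$p_value)
    }
  }
  out$mann_whitney <- mw
  for (g in unique(att$group)) {
    gg <- att[att$group == g, ]
    if (nrow(gg) >= 3 && stats::sd(gg$n_criteria) > 0) {
      for (cl in crit) {
        if (stats::sd(gg[[cl]]) > 0)
          out$correlations[[paste(g, cl, sep = ".")]] <-
            pearson_correlation(gg[[cl]], gg$n_criteria)
      }
    }
  }
  out
}
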