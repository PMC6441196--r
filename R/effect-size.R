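# Conversions from reported trial summaries (confidence intervals, means,
# SDs, event counts, margins) to the standardized statistics the Bayes
# factor core consumes.

#' Two-arm continuous-outcome trial summary
#'
#' @param n1,n2 Arm sample sizes (>= 2).
#' @param m1,m2 Arm means, in outcome units.
#' @param sd1,sd2 Arm standard deviations (both or neither).
#' @param se_diff Standard error of the mean difference, e.g. recovered
#'   from a reported confidence interval via [se_from_ci()].  Exactly one
#'   of the SD pair or `se_diff` must be supplied.
#' @return An object of class `"trial_summary_continuous"`.
#' @examples
#' trial_summary_continuous(203, 201, 63.6, 68.1, se_diff = 11 / 1.966)
#' trial_summary_continuous(32, 33, 13.6, 17.1, sd1 = 9.8, sd2 = 8)
#' @export
trial_summary_continuous <- function(n1, n2, m1, m2,
                                     sd1 = NULL, sd2 = NULL, se_diff = NULL) {
  if (n1 < 2 || n2 < 2) stop("arm sizes must be at least 2", call. = FALSE)
  have_sd <- !is.null(sd1) || !is.null(sd2)
  have_se <- !is.null(se_diff)
  if (have_sd == have_se) {
    stop("supply exactly one of {sd1 & sd2} or se_diff", call. = FALSE)
  }
  if (have_sd) {
    if (is.null(sd1) || is.null(sd2)) stop("both sd1 and sd2 are required",
                                           call. = FALSE)
    if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive",
                                   call. = FALSE)
  } else if (se_diff <= 0) {
    stop("se_diff must be positive", call. = FALSE)
  }
  structure(list(n1 = n1, n2 = n2, m1 = m1, m2 = m2,
                 sd1 = sd1, sd2 = sd2, se_diff = se_diff),
            class = "trial_summary_continuous")
}

#' Two-arm dichotomous-outcome trial summary
#'
#' @param n1,n2 Arm sample sizes (>= 1).
#' @param k1,k2 Event counts, `0 <= k <= n` per arm.
#' @return An object of class `"trial_summary_binomial"`.
#' @examples
#' trial_summary_binomial(656, 739, 59, 82)
#' @export
trial_summary_binomial <- function(n1, n2, k1, k2) {
  if (n1 < 1 || n2 < 1) stop("arm sizes must be at least 1", call. = FALSE)
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) {
    stop("event counts must satisfy 0 <= k <= n in each arm", call. = FALSE)
  }
  structure(list(n1 = n1, n2 = n2, k1 = k1, k2 = k2),
            class = "trial_summary_binomial")
}

#' Standard error from a reported confidence interval
#'
#' `(upper - lower) / 2` divided by the two-sided normal quantile of the
#' confidence level, e.g. 1.959964 at 95 percent.
#'
#' @param lower,upper Interval endpoints, in outcome units.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return The standard error of the estimate, in outcome units.
#' @examples
#' se_from_ci(-6.5, 15.5)   # about 5.6
#' @export
se_from_ci <- function(lower, upper, level = 0.95) {
  if (!is.finite(lower) || !is.finite(upper) || upper <= lower) {
    stop("`upper` must exceed `lower`", call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  (upper - lower) / 2 / z
}

#' t statistic for a mean difference against a null value
#'
#' @param m1,m2 Group means.
#' @param se_diff Standard error of the difference, positive.
#' @param null_diff Null value of `m1 - m2` (0 for superiority, the raw
#'   margin for non-inferiority).
#' @return The t (or Z-as-t) statistic `(m1 - m2 - null_diff) / se_diff`.
#' @examples
#' t_from_se(63.6, 68.1, 5.6)   # -0.80
#' @export
t_from_se <- function(m1, m2, se_diff, null_diff = 0) {
  if (se_diff <= 0) stop("`se_diff` must be positive", call. = FALSE)
  (m1 - m2 - null_diff) / se_diff
}

#' Pooled standard deviation of two groups
#'
#' @param sd1,sd2 Group standard deviations.
#' @param n1,n2 Group sizes (>= 2).
#' @return `sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2))`.
#' @examples
#' pooled_sd(9.8, 8, 32, 33)
#' @export
pooled_sd <- function(sd1, sd2, n1, n2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive",
                                 call. = FALSE)
  sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
}

#' Cohen's h for a margin on two proportions
#'
#' Standardizes a margin expressed in proportion points through the
#' arcsine-square-root (variance-stabilizing) transform, anchored at the
#' pooled event proportion of the two compared arms:
#' `2 asin(sqrt(p)) - 2 asin(sqrt(p - margin))`.
#'
#' @param summary A [trial_summary_binomial()].
#' @param margin Margin in proportion points (e.g. 0.03 for 3 percentage
#'   points); may be 0.
#' @return The standardized margin (Cohen's h units).
#' @examples
#' cohens_h_margin(trial_summary_binomial(656, 739, 59, 82), 0.03)  # 0.11
#' @export
cohens_h_margin <- function(summary, margin) {
  if (!inherits(summary, "trial_summary_binomial")) {
    stop("`summary` must be a trial_summary_binomial", call. = FALSE)
  }
  pbar <- (summary$k1 + summary$k2) / (summary$n1 + summary$n2)
  shifted <- pbar - margin
  if (pbar <= 0 || pbar >= 1 || shifted < 0 || shifted > 1) {
    stop("pooled proportion minus margin falls outside [0, 1]", call. = FALSE)
  }
  2 * asin(sqrt(pbar)) - 2 * asin(sqrt(shifted))
}

#' Z statistic for a difference of two proportions against a margin
#'
#' Normal-approximation statistic with a pooled-proportion standard error:
#' `(k1/n1 - k2/n2 - margin) / sqrt(pbar (1 - pbar) (1/n1 + 1/n2))`.
#'
#' @inheritParams cohens_h_margin
#' @return The Z statistic (treated downstream as t with
#'   `df = n1 + n2 - 2`).
#' @examples
#' z_two_proportions(trial_summary_binomial(656, 739, 59, 82), 0.03)  # -3.16
#' @export
z_two_proportions <- function(summary, margin = 0) {
  if (!inherits(summary, "trial_summary_binomial")) {
    stop("`summary` must be a trial_summary_binomial", call. = FALSE)
  }
  pbar <- (summary$k1 + summary$k2) / (summary$n1 + summary$n2)
  if (pbar <= 0 || pbar >= 1) {
    stop("pooled proportion must lie strictly inside (0, 1)", call. = FALSE)
  }
  se <- sqrt(pbar * (1 - pbar) * (1 / summary$n1 + 1 / summary$n2))
  (summary$k1 / summary$n1 - summary$k2 / summary$n2 - margin) / se
}

#' Effective sample size of a two-sample comparison
#'
#' @param n1,n2 Arm sizes (>= 1).
#' @return `n1 * n2 / (n1 + n2)`, the single-sample equivalent governing
#'   the precision of the mean difference.
#' @examples
#' n_eff_two_sample(203, 201)
#' @export
n_eff_two_sample <- function(n1, n2) {
  if (n1 < 1 || n2 < 1) stop("arm sizes must be at least 1", call. = FALSE)
  n1 * n2 / (n1 + n2)
}

# Internal: t statistic, df and n_eff for a continuous summary against a
# raw-unit null difference.  Uses se_diff when supplied, else the pooled-SD
# standard error.
.stat_from_continuous <- function(summary, null_diff = 0) {
  se <- if (!is.null(summary$se_diff)) {
    summary$se_diff
  } else {
    pooled_sd(summary$sd1, summary$sd2, summary$n1, summary$n2) *
      sqrt(1 / summary$n1 + 1 / summary$n2)
  }
  test_statistic(
    t = t_from_se(summary$m1, summary$m2, se, null_diff),
    df = summary$n1 + summary$n2 - 2,
    n_eff = n_eff_two_sample(summary$n1, summary$n2)
  )
}
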