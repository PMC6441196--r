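# Design-level workflows: chain the summary-statistic conversions and the
# Bayes-factor core into a complete report for the three canonical two-arm
# trial designs.

.bf_report <- function(design, inputs, prior, statistics, bayes_factors,
                       interpretation, notes = character()) {
  structure(list(design = design, inputs = inputs, prior = prior,
                 statistics = statistics, bayes_factors = bayes_factors,
                 interpretation = interpretation, notes = notes),
            class = "bf_report")
}

#' Evidence band for a Bayes factor
#'
#' Maps the magnitude of a Bayes factor to the conventional evidence
#' labels: 1-3 "anecdotal" (not worth more than a bare mention), 3-20
#' "positive", 20-150 "strong", above 150 "overwhelming".  Values below 1
#' are classified by their reciprocal (the same strength of evidence, for
#' the other hypothesis).  Bands are half-open `[lower, upper)`;
#' "overwhelming" is a presentation-only extension of the standard scale.
#'
#' @param bf A positive Bayes factor.
#' @return One of `"anecdotal"`, `"positive"`, `"strong"`,
#'   `"overwhelming"`.
#' @examples
#' classify_bf(11.04)   # "positive"
#' classify_bf(1 / 39)  # "strong"
#' @export
classify_bf <- function(bf) {
  if (!is.numeric(bf) || length(bf) != 1L || !is.finite(bf) || bf <= 0) {
    stop("`bf` must be a single positive number", call. = FALSE)
  }
  b <- max(bf, 1 / bf)
  if (b < 3) "anecdotal" else if (b < 20) "positive" else if (b < 150) "strong"
  else "overwhelming"
}

#' Superiority analysis
#'
#' Computes one- and two-sided default Bayes factors against the point
#' null of no effect, with a zero-centered Cauchy prior on the
#' standardized mean difference.  The statistic is formed from the summary
#' via the reported standard error of the difference (e.g. recovered from
#' a confidence interval) or from the pooled arm SDs.
#'
#' @param summary A [trial_summary_continuous()].
#' @param prior A [cauchy_prior()]; its location must be 0 for a
#'   superiority test.
#' @param side Pre-specified direction of superiority on the raw scale:
#'   `"lower"` if superiority means `m1 - m2 < 0` (e.g. a shorter hospital
#'   stay), `"upper"` otherwise.
#' @return A `"bf_report"` with the two-sided BF10 and both one-sided
#'   Bayes factors.
#' @examples
#' adren <- trial_summary_continuous(203, 201, 63.6, 68.1,
#'                                   se_diff = se_from_ci(-6.5, 15.5))
#' analyze_superiority(adren)
#' @export
analyze_superiority <- function(summary, prior = cauchy_prior(),
                                side = c("lower", "upper")) {
  side <- match.arg(side)
  if (!inherits(summary, "trial_summary_continuous")) {
    stop("`summary` must be a trial_summary_continuous", call. = FALSE)
  }
  .assert_prior(prior)
  if (prior$location != 0) {
    stop("superiority analyses use a zero-centered prior", call. = FALSE)
  }
  stat <- .stat_from_continuous(summary, null_diff = 0)
  two <- bf10_eq4(stat, prior)
  lower <- bf_one_sided(stat, prior, "lower")
  upper <- bf_one_sided(stat, prior, "upper")
  directional <- if (side == "lower") lower else upper
  bfs <- list(two_sided = two, lower = lower, upper = upper)
  .bf_report(
    design = "superiority",
    inputs = c(unclass(summary), list(side = side)),
    prior = prior,
    statistics = list(t = stat$t, df = stat$df, n_eff = stat$n_eff),
    bayes_factors = bfs,
    interpretation = classify_bf(directional$bf10)
  )
}

#' Equivalence analysis
#'
#' Quantifies evidence in favor of no effect.  The primary quantity is the
#' two-sided point-null Bayes factor BF01; when an equivalence half-width
#' `equiv_c` is supplied, the interval-null Bayes factor for
#' \eqn{-c < \delta < c} versus its complement is reported as well.
#'
#' @inheritParams analyze_superiority
#' @param equiv_c Optional equivalence half-width in standardized
#'   effect-size units.
#' @return A `"bf_report"`.
#' @examples
#' rbc <- trial_summary_continuous(538, 560, 8.516, 8.683, sd1 = 3.6, sd2 = 3.6)
#' analyze_equivalence(rbc, equiv_c = 0.05)
#' @export
analyze_equivalence <- function(summary, prior = cauchy_prior(),
                                equiv_c = NULL) {
  if (!inherits(summary, "trial_summary_continuous")) {
    stop("`summary` must be a trial_summary_continuous", call. = FALSE)
  }
  .assert_prior(prior)
  if (prior$location != 0) {
    stop("equivalence analyses use a zero-centered prior", call. = FALSE)
  }
  stat <- .stat_from_continuous(summary, null_diff = 0)
  two <- bf10_eq4(stat, prior)
  bfs <- list(two_sided = two)
  if (!is.null(equiv_c)) {
    bfs$interval <- bf_interval(stat, prior, half_width = equiv_c)
  }
  .bf_report(
    design = "equivalence",
    inputs = c(unclass(summary), list(equiv_c = equiv_c)),
    prior = prior,
    statistics = list(t = stat$t, df = stat$df, n_eff = stat$n_eff),
    bayes_factors = bfs,
    interpretation = classify_bf(two$bf01)
  )
}

#' Non-inferiority analysis
#'
#' Standardizes the margin (Cohen's d for continuous outcomes via the
#' pooled SD, Cohen's h for dichotomous outcomes via the pooled-proportion
#' arcsine transform), evaluates the statistic against the margin point,
#' recenters the Cauchy prior at the standardized margin distance, and
#' reports the two one-sided Bayes factors together with the composite
#' non-inferior-versus-inferior factor obtained by transitivity.
#'
#' Conventions: `margin` is always positive; `higher_is_worse` states
#' whether larger outcome values (or events, for counts) are harmful.
#' Internally the harmful direction is mapped to the upper side, so the
#' composite factor always reads "non-inferior over inferior".
#'
#' @param summary A [trial_summary_continuous()] with arm SDs, or a
#'   [trial_summary_binomial()].
#' @param margin Positive non-inferiority margin, in raw outcome units
#'   (continuous) or proportion points (dichotomous).
#' @param higher_is_worse `TRUE` (default) when larger outcomes/events are
#'   harmful (mortality, symptom scores); `FALSE` when they are beneficial.
#' @param prior A zero-centered [cauchy_prior()] giving the scale; its
#'   location is set internally to the standardized margin.
#' @return A `"bf_report"` whose `bayes_factors` hold the composite
#'   `noninferiority` factor and its `lower`/`upper` components (in the
#'   margin-shifted frame where the non-inferior side is lower).
#' @examples
#' cap <- trial_summary_binomial(656, 739, 59, 82)
#' analyze_noninferiority(cap, margin = 0.03)
#' @export
analyze_noninferiority <- function(summary, margin, higher_is_worse = TRUE,
                                   prior = cauchy_prior()) {
  .assert_prior(prior)
  if (prior$location != 0) {
    stop("supply a zero-centered prior; the margin shift is applied internally",
         call. = FALSE)
  }
  if (!is.numeric(margin) || length(margin) != 1L || !is.finite(margin) ||
      margin <= 0) {
    stop("`margin` must be a single positive number (direction is carried by `higher_is_worse`)",
         call. = FALSE)
  }

  if (inherits(summary, "trial_summary_continuous")) {
    if (is.null(summary$sd1)) {
      stop("non-inferiority for continuous outcomes needs arm SDs to standardize the margin",
           call. = FALSE)
    }
    sd_p <- pooled_sd(summary$sd1, summary$sd2, summary$n1, summary$n2)
    std_margin <- margin / sd_p
    null_diff <- if (higher_is_worse) margin else -margin
    stat <- .stat_from_continuous(summary, null_diff = null_diff)
    outcome <- "continuous"
  } else if (inherits(summary, "trial_summary_binomial")) {
    std_margin <- cohens_h_margin(summary, margin)
    z <- z_two_proportions(summary, if (higher_is_worse) margin else -margin)
    stat <- test_statistic(t = z, df = summary$n1 + summary$n2 - 2,
                           n_eff = n_eff_two_sample(summary$n1, summary$n2))
    outcome <- "binomial"
  } else {
    stop("`summary` must be a trial_summary_continuous or trial_summary_binomial",
         call. = FALSE)
  }

  # mirror the higher-is-better case onto the canonical frame in which the
  # margin sits on the positive side and non-inferiority is the lower side
  if (!higher_is_worse) {
    stat <- test_statistic(-stat$t, stat$df, stat$n_eff)
  }
  shifted <- cauchy_prior(location = std_margin, scale = prior$scale)
  composite <- bf_noninferiority(stat, shifted)
  comps <- attr(composite, "components")

  .bf_report(
    design = "noninferiority",
    inputs = c(unclass(summary),
               list(margin = margin, higher_is_worse = higher_is_worse,
                    outcome = outcome)),
    prior = shifted,
    statistics = list(t = stat$t, df = stat$df, n_eff = stat$n_eff,
                      std_margin = std_margin),
    bayes_factors = list(noninferiority = composite,
                         lower = comps$lower, upper = comps$upper),
    interpretation = classify_bf(composite$bf10)
  )
}

#' @export
print.bf_report <- function(x, ...) {
  cat(sprintf("Bayesian %s analysis (two-arm trial)\n", x$design))
  cat(sprintf("  prior: Cauchy(location = %g, scale = %g)\n",
              x$prior$location, x$prior$scale))
  st <- x$statistics
  cat(sprintf("  statistic: t = %.4f, df = %g, n_eff = %.2f%s\n",
              st$t, st$df, st$n_eff,
              if (!is.null(st$std_margin))
                sprintf(", standardized margin = %.4f", st$std_margin) else ""))
  labels <- c(two_sided = "BF10 (two-sided)",
              lower = "BF-0 (lower one-sided)",
              upper = "BF+0 (upper one-sided)",
              interval = "BF01 (interval null)",
              noninferiority = "BF-+ (non-inferior vs inferior)")
  for (nm in names(x$bayes_factors)) {
    bf <- x$bayes_factors[[nm]]
    shown <- if (nm == "interval") bf$bf01 else bf$bf10
    cat(sprintf("  %-34s %10.2f   (reciprocal %.2f)\n",
                labels[[nm]], shown, 1 / shown))
  }
  cat(sprintf("  evidence: %s\n", x$interpretation))
  if (length(x$notes)) for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}
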