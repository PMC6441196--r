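#' Cauchy effect-size prior
#'
#' Constructs the (possibly location-shifted) Cauchy prior on the
#' standardized effect size \eqn{\delta} that defines the default
#' Jeffreys-Zellner-Siow alternative hypothesis.  The Cauchy is the
#' analytic marginal of a normal prior on \eqn{\delta} whose variance
#' \eqn{g} follows a scaled inverse-chi-square distribution with one
#' degree of freedom; the Bayes factor integrates \eqn{g} out.
#'
#' The default scale is \eqn{\sqrt{2}/2}, the value used by the
#' BayesFactor/JASP ecosystem (and the value that reproduces the worked
#' reanalyses shipped with this package; see `vignette("trial-bayes-factors")`).
#' A scale of 1 recovers Jeffreys' original choice.  A non-zero location
#' recenters the prior away from the point null, which is how
#' non-inferiority margins enter the computation.
#'
#' @param location Center of the prior in standardized effect-size units
#'   (Cohen's d or h).  Zero for superiority/equivalence; the signed
#'   standardized margin distance for non-inferiority.
#' @param scale Cauchy scale parameter, in effect-size units.  Must be
#'   positive.
#' @return An object of class `"cauchy_prior"` with fields `location`
#'   and `scale`.
#' @examples
#' cauchy_prior()                 # default zero-centered prior
#' cauchy_prior(location = 0.22)  # shifted to a standardized margin
#' @seealso [bf10_eq4()], [analyze_noninferiority()]
#' @export
cauchy_prior <- function(location = 0, scale = sqrt(2) / 2) {
  if (!is.numeric(location) || length(location) != 1L || !is.finite(location)) {
    stop("`location` must be a single finite number", call. = FALSE)
  }
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop("`scale` must be a single positive number", call. = FALSE)
  }
  structure(list(location = as.numeric(location), scale = as.numeric(scale)),
            class = "cauchy_prior")
}

#' @export
print.cauchy_prior <- function(x, ...) {
  cat(sprintf("Cauchy effect-size prior: location = %g, scale = %g\n",
              x$location, x$scale))
  invisible(x)
}

.assert_prior <- function(prior) {
  if (!inherits(prior, "cauchy_prior")) {
    stop("`prior` must be created with cauchy_prior()", call. = FALSE)
  }
  prior
}

#' Test statistic with its effective sample size
#'
#' Bundles a t statistic (or a Z statistic treated as t) with its degrees
#' of freedom and the effective sample size that scales the noncentrality,
#' \eqn{ncp = \delta\sqrt{n_{eff}}}.  For a two-sample comparison use
#' `df = n1 + n2 - 2` and `n_eff = n1 n2 / (n1 + n2)`.
#'
#' @param t Observed statistic.  Must be finite.
#' @param df Degrees of freedom, positive.
#' @param n_eff Effective sample size, positive.
#' @return An object of class `"test_statistic"`.
#' @examples
#' test_statistic(t = -0.80, df = 402, n_eff = 203 * 201 / 404)
#' @export
test_statistic <- function(t, df, n_eff) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t)) {
    stop("`t` must be a single finite number (NaN/NA rejected)", call. = FALSE)
  }
  if (!is.numeric(df) || length(df) != 1L || !is.finite(df) || df <= 0) {
    stop("`df` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(n_eff) || length(n_eff) != 1L || !is.finite(n_eff) ||
      n_eff <= 0) {
    stop("`n_eff` must be a single positive number", call. = FALSE)
  }
  structure(list(t = as.numeric(t), df = as.numeric(df),
                 n_eff = as.numeric(n_eff)),
            class = "test_statistic")
}

#' @export
print.test_statistic <- function(x, ...) {
  cat(sprintf("t = %g on df = %g (effective n = %g)\n", x$t, x$df, x$n_eff))
  invisible(x)
}

# Stricter gate applied at Bayes-factor evaluation time.  df < 1 cannot
# arise from a real two-arm summary; n_eff may be arbitrarily small (the
# uninformative limit n_eff -> 0 gives a Bayes factor of exactly 1) but
# must be positive.
.assert_stat <- function(stat) {
  if (!inherits(stat, "test_statistic")) {
    stop("`stat` must be created with test_statistic()", call. = FALSE)
  }
  if (stat$df < 1) stop("df < 1: too few observations for a Bayes factor",
                        call. = FALSE)
  stat
}
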