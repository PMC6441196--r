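# Core marginal-likelihood machinery: the JZS Bayes factor as a
# one-dimensional integral over the mixing variance g, evaluated in log
# space.  The integrand is the marginal density of t given g (a rescaled
# noncentral t) times the scaled inverse-chi-square density of g, divided
# by the central-t null marginal; shared normalizing constants cancel.

# log 1F1(a; b; x) for x >= 0 by direct series in log space.  All terms are
# positive, so a running log-sum-exp is exact up to rounding.  Terms peak
# near k ~ sqrt(a x); the loop stops once past the peak and 40 nats below
# the accumulated sum.
.log1F1 <- function(a, b, x) {
  if (x < 0) stop("internal: .log1F1 requires x >= 0")
  if (x == 0) return(0)
  lx <- log(x)
  lt <- 0
  lsum <- 0
  k <- 0
  repeat {
    lt <- lt + log(a + k) + lx - log(b + k) - log1p(k)
    m <- max(lsum, lt)
    lsum <- m + log(exp(lsum - m) + exp(lt - m))
    k <- k + 1
    if (k > 5 && lt < lsum - 40 && (a + k) * x < (b + k) * (k + 1)) break
    if (k > 100000L) {
      stop(sprintf("1F1 series failed to converge (a=%g, b=%g, x=%g)", a, b, x),
           call. = FALSE)
    }
  }
  lsum
}

# The "bracket" of the g-integrand: for a t-type statistic tp with df nu and
# noncentrality a,
#   Gamma((nu+1)/2) 1F1((nu+1)/2; 1/2; x)
#     + sqrt(2) a tp / sqrt(nu + tp^2) * Gamma(nu/2 + 1) 1F1(nu/2+1; 3/2; x),
# with x = a^2 tp^2 / (2 (nu + tp^2)).  When a * tp < 0 the two terms nearly
# cancel in the far tail; there we fall back to an equivalent, strictly
# positive Laplace-type integral representation (see .log_bracket_integral).
.log_bracket <- function(nu, tp, a) {
  a1 <- (nu + 1) / 2
  x <- a * a * tp * tp / (2 * (nu + tp * tp))
  A <- lgamma(a1) + .log1F1(a1, 0.5, x)
  c2 <- sqrt(2) * a * tp / sqrt(nu + tp * tp)
  if (c2 == 0) return(A)
  B <- log(abs(c2)) + lgamma(nu / 2 + 1) + .log1F1(nu / 2 + 1, 1.5, x)
  if (c2 > 0) {
    m <- max(A, B)
    return(m + log(exp(A - m) + exp(B - m)))
  }
  # difference of nearly equal terms: safe only while the ratio stays away
  # from 1 (amplification of rounding error bounded by ~1e3)
  if (B - A < log1p(-1e-3)) {
    return(A + log1p(-exp(B - A)))
  }
  .log_bracket_integral(nu, tp, a)
}

# Exact alternative for the bracket, derived from the defining integral of
# the noncentral-t density over the chi scale variable s:
#   log bracket = (1-nu)/2 log 2 + (nu+1)/2 log(nu + tp^2) + a^2/2
#                 + log \int_0^Inf s^nu exp(-((tp^2+nu)s^2 - 2 a tp s + a^2)/2) ds
# The integrand is log-concave with mode s*; it is rescaled by its maximum
# before quadrature so no overflow can occur.
.log_bracket_integral <- function(nu, tp, a) {
  q <- tp * tp + nu
  lf <- function(s) nu * log(s) - 0.5 * (q * s * s - 2 * a * tp * s + a * a)
  smode <- (a * tp + sqrt(a * a * tp * tp + 4 * nu * q)) / (2 * q)
  M <- lf(smode)
  I <- stats::integrate(function(s) exp(vapply(s, lf, numeric(1)) - M),
                        lower = 0, upper = Inf,
                        rel.tol = 1e-12, abs.tol = 0, subdivisions = 400L)
  (1 - nu) / 2 * log(2) + (nu + 1) / 2 * log(q) + a * a / 2 + M + log(I$value)
}

# log of the g-integrand (numerator of the Bayes-factor ratio, shared
# constants dropped).  n = effective sample size, nu = degrees of freedom,
# mu = prior location, r = prior scale.
.log_g_integrand <- function(g, t, n, nu, mu, r) {
  s2 <- 1 + n * g
  core <- -0.5 * log(s2) -
    mu * mu / (2 * (1 / n + g)) -
    (nu + 1) / 2 * log1p(t * t / (s2 * nu))
  # bracket arguments in the rescaled frame: tp = t / sqrt(1+ng),
  # a = mu sqrt(n) / sqrt(1+ng)
  tp <- t / sqrt(s2)
  a <- mu * sqrt(n) / sqrt(s2)
  lbr <- .log_bracket(nu, tp, a)
  # scaled inverse-chi-square (nu=1) mixing density of g
  lmix <- log(r) - 0.5 * log(2) - lgamma(0.5) - 1.5 * log(g) - r * r / (2 * g)
  core + lbr + lmix
}

.bf_value <- function(bf10, direction, abs_err = NA_real_, log_bf10 = log(bf10)) {
  structure(list(bf10 = bf10,
                 log_bf10 = log_bf10,
                 bf01 = 1 / bf10,
                 direction = direction,
                 integration_abs_err = abs_err),
            class = "bf_value")
}

#' @export
print.bf_value <- function(x, ...) {
  lab <- switch(x$direction,
                two_sided = "BF10 (two-sided)",
                lower     = "BF-0 (delta < 0 vs delta = 0)",
                upper     = "BF+0 (delta > 0 vs delta = 0)",
                interval  = "BF10 (outside vs inside interval)",
                composite = "BF-+ (non-inferior vs inferior)",
                "BF10")
  cat(sprintf("%s = %.2f  (reciprocal %.2f, log BF = %.4f)\n",
              lab, x$bf10, x$bf01, x$log_bf10))
  invisible(x)
}

#' Two-sided default Bayes factor by mixing-variance quadrature
#'
#' Computes the Bayes factor BF10 of the Cauchy-prior alternative over the
#' point null \eqn{\delta = 0} by one-dimensional adaptive quadrature over
#' the normal-prior mixing variance \eqn{g}.  Conditional on \eqn{g}, the
#' statistic follows a rescaled noncentral-t distribution; averaging over
#' the scaled inverse-chi-square distribution of \eqn{g} yields the Cauchy
#' marginal likelihood, which is divided by the central-t null marginal.
#'
#' The integral is transformed to the unit interval via
#' \eqn{u = g/(1+g)} and the integrand is evaluated in log space
#' (log-gamma, log-space confluent hypergeometric series, and a positive
#' integral representation where the series would cancel), so the routine
#' is stable for large samples and extreme statistics.
#'
#' @param stat A [test_statistic()].
#' @param prior A [cauchy_prior()].
#' @return A `"bf_value"` with fields `bf10`, `log_bf10`, `bf01`,
#'   `direction = "two_sided"`, and the quadrature diagnostic
#'   `integration_abs_err` (relative).
#' @examples
#' # adrenaline vs saline in acute bronchiolitis (length of stay, hours)
#' stat <- test_statistic(t = -0.80, df = 402, n_eff = 203 * 201 / 404)
#' bf10_eq4(stat, cauchy_prior())
#' @seealso [oracle_bf()] for an independent check by direct integration
#'   over the effect size.
#' @export
bf10_eq4 <- function(stat, prior = cauchy_prior()) {
  .assert_stat(stat)
  .assert_prior(prior)
  t <- stat$t
  n <- stat$n_eff
  nu <- stat$df
  mu <- prior$location
  r <- prior$scale

  lfu <- function(u) .log_g_integrand(u / (1 - u), t, n, nu, mu, r) -
    2 * log1p(-u)
  # locate the peak on a probe grid so the integrand can be rescaled
  us <- seq(1e-6, 1 - 1e-6, length.out = 301L)
  lv <- vapply(us, function(u) {
    v <- tryCatch(lfu(u), error = function(e) -Inf)
    if (is.nan(v)) -Inf else v
  }, numeric(1))
  M <- max(lv)
  if (!is.finite(M)) {
    stop("non-convergent quadrature: g-integrand not finite anywhere on (0, 1)",
         call. = FALSE)
  }
  val <- tryCatch(
    stats::integrate(function(u) {
      vapply(u, function(ui) {
        v <- lfu(ui) - M
        if (is.nan(v)) 0 else exp(v)
      }, numeric(1))
    }, lower = 0, upper = 1,
    rel.tol = 1e-8, abs.tol = 1e-10, subdivisions = 400L),
    error = function(e) {
      stop(sprintf("non-convergent quadrature over the mixing variance: %s",
                   conditionMessage(e)), call. = FALSE)
    })
  if (val$value <= 0) {
    stop("non-convergent quadrature: numerator integral collapsed to zero",
         call. = FALSE)
  }
  log_null <- lgamma((nu + 1) / 2) - (nu + 1) / 2 * log1p(t * t / nu)
  log_bf <- M + log(val$value) - log_null
  .bf_value(exp(log_bf), "two_sided",
            abs_err = val$abs.error / val$value, log_bf10 = log_bf)
}

#' One-sided default Bayes factor
#'
#' Bayes factor of the directional alternative (\eqn{\delta < 0} or
#' \eqn{\delta > 0}) against the point null \eqn{\delta = 0}, computed by
#' mass decomposition of the two-sided Bayes factor:
#' `bf10_eq4 * posterior mass on the side / prior mass on the side`.
#' With a zero-centered prior each prior half is exactly 1/2 and the two
#' one-sided factors average to the two-sided one.
#'
#' @inheritParams bf10_eq4
#' @param side `"lower"` for \eqn{\delta < 0}, `"upper"` for
#'   \eqn{\delta > 0}.
#' @return A `"bf_value"` with `direction` equal to `side`.
#' @examples
#' stat <- test_statistic(t = -0.80, df = 402, n_eff = 203 * 201 / 404)
#' bf_one_sided(stat, cauchy_prior(), "lower")   # BF-0 = 0.24
#' @export
bf_one_sided <- function(stat, prior = cauchy_prior(),
                         side = c("lower", "upper")) {
  side <- match.arg(side)
  two <- bf10_eq4(stat, prior)
  post <- posterior_delta(stat, prior)
  mass_lower <- post$mass(-Inf, 0)
  prior_lower <- stats::pcauchy(0, prior$location, prior$scale)
  if (side == "lower") {
    pm <- mass_lower
    prm <- prior_lower
  } else {
    pm <- 1 - mass_lower
    prm <- 1 - prior_lower
  }
  if (pm < 1e-280) {
    warning(sprintf(
      "posterior mass on the %s side underflows (%.3g); log-scale result only",
      side, pm), call. = FALSE)
  }
  log_bf <- two$log_bf10 + log(pm) - log(prm)
  .bf_value(exp(log_bf), side,
            abs_err = max(two$integration_abs_err, post$norm_abs_err),
            log_bf10 = log_bf)
}

#' Interval-null Bayes factor
#'
#' Bayes factor BF01 of an interval null \eqn{-c < \delta < c} against its
#' complement, as the ratio of posterior to prior odds of the interval:
#' `[post(inside)/prior(inside)] / [post(outside)/prior(outside)]`.
#' As \eqn{c \to 0} this converges to the point-null BF01 (the
#' Savage-Dickey limit); if the requested interval is so narrow that the
#' masses underflow, the point Savage-Dickey density ratio is returned with
#' a warning.
#'
#' @inheritParams bf10_eq4
#' @param half_width Positive half-width \eqn{c} of the interval, in
#'   standardized effect-size units.
#' @return A `"bf_value"` with `direction = "interval"`; `bf10` is
#'   oriented as outside-over-inside so that `bf01` is the equivalence
#'   Bayes factor usually reported.
#' @examples
#' # red-cell storage equivalence reanalysis, c = 0.05
#' stat <- test_statistic(t = -0.77, df = 1096, n_eff = 538 * 560 / 1098)
#' bf_interval(stat, cauchy_prior(), half_width = 0.05)$bf01   # about 19
#' @export
bf_interval <- function(stat, prior = cauchy_prior(), half_width) {
  .assert_stat(stat)
  .assert_prior(prior)
  if (!is.numeric(half_width) || length(half_width) != 1L ||
      !is.finite(half_width) || half_width <= 0) {
    stop("`half_width` must be a single positive number", call. = FALSE)
  }
  post <- posterior_delta(stat, prior)
  p_in <- post$mass(-half_width, half_width)
  pr_in <- stats::pcauchy(half_width, prior$location, prior$scale) -
    stats::pcauchy(-half_width, prior$location, prior$scale)
  if (p_in < 1e-290 || pr_in < 1e-290) {
    warning("interval masses underflow; returning the point Savage-Dickey ratio",
            call. = FALSE)
    bf01 <- post$density(0) / stats::dcauchy(0, prior$location, prior$scale)
    return(.bf_value(1 / bf01, "interval", abs_err = post$norm_abs_err))
  }
  # outside masses computed directly so wide intervals do not cancel
  p_out <- post$mass(-Inf, -half_width) + post$mass(half_width, Inf)
  pr_out <- stats::pcauchy(-half_width, prior$location, prior$scale) +
    stats::pcauchy(half_width, prior$location, prior$scale,
                   lower.tail = FALSE)
  if (p_out <= 0 || pr_out <= 0) {
    stop("interval so wide that the complement has no posterior mass",
         call. = FALSE)
  }
  bf01 <- (p_in / pr_in) / (p_out / pr_out)
  .bf_value(1 / bf01, "interval", abs_err = post$norm_abs_err)
}

#' Composite non-inferiority Bayes factor
#'
#' In the margin-shifted frame (the margin point at \eqn{\delta = 0}, the
#' prior recentered at the standardized margin distance), the evidence for
#' the non-inferior side over the inferior side follows by transitivity:
#' `BF(-,+) = BF(-,0) x BF(0,+) = bf_one_sided(lower) / bf_one_sided(upper)`.
#'
#' @param stat_at_margin A [test_statistic()] computed against the margin
#'   point (classical non-inferiority null).
#' @param prior A [cauchy_prior()] whose location is the signed
#'   standardized distance from the margin point to the no-effect point
#'   (positive when the margin sits on the harmful side; see
#'   [analyze_noninferiority()], which sets this up).
#' @return A `"bf_value"` with `direction = "composite"` plus a
#'   `components` attribute holding the two one-sided `"bf_value"`s.
#' @examples
#' # internet-delivered vs group CBT, 2-point MADRS margin (d = 0.224)
#' stat <- test_statistic(t = -2.48, df = 63, n_eff = 32 * 33 / 65)
#' bf_noninferiority(stat, cauchy_prior(location = 0.224))
#' @export
bf_noninferiority <- function(stat_at_margin, prior) {
  lower <- bf_one_sided(stat_at_margin, prior, "lower")
  upper <- bf_one_sided(stat_at_margin, prior, "upper")
  log_bf <- lower$log_bf10 - upper$log_bf10
  out <- .bf_value(exp(log_bf), "composite",
                   abs_err = max(lower$integration_abs_err,
                                 upper$integration_abs_err),
                   log_bf10 = log_bf)
  attr(out, "components") <- list(lower = lower, upper = upper)
  out
}
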