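# Independent brute-force oracle and synthetic trial generators.  The
# oracle integrates directly over the effect size delta and never touches
# the mixing-variance route, so the two paths cross-check each other.

#' Brute-force Bayes factor by integration over the effect size
#'
#' Computes BF10 as the ratio of the prior-averaged noncentral-t likelihood
#' to the central-t null likelihood,
#' \deqn{BF_{10} = \frac{\int f_{nct}(t; df, \delta\sqrt{n_{eff}})\,
#'   Cauchy(\delta; loc, scale)\, d\delta}{f_t(t; df)},}
#' by adaptive quadrature over \eqn{\delta} with a tangent substitution.
#' This route is deliberately independent of [bf10_eq4()] (which
#' integrates over the mixing variance) and serves as its oracle in the
#' test suite.
#'
#' @inheritParams bf10_eq4
#' @return An object of class `"oracle_result"`: list with `bf10` and
#'   `quadrature_abs_err`.
#' @examples
#' st <- test_statistic(1, df = 18, n_eff = 10)
#' oracle_bf(st, cauchy_prior(0, 1))
#' @export
oracle_bf <- function(stat, prior = cauchy_prior()) {
  .assert_stat(stat)
  .assert_prior(prior)
  t <- stat$t
  nu <- stat$df
  sqn <- sqrt(stat$n_eff)
  tau <- 1 / prior$scale^2
  c0 <- (sqn * t + tau * prior$location) / (stat$n_eff + tau)
  w <- sqrt((abs(t) + 40) / sqn / sqrt(stat$n_eff + tau))
  num <- tryCatch(
    stats::integrate(function(th) {
      vapply(th, function(thi) {
        d <- c0 + w * tan(thi)
        if (!is.finite(d)) return(0)
        v <- suppressWarnings(stats::dt(t, nu, ncp = d * sqn)) *
          stats::dcauchy(d, prior$location, prior$scale) * w / cos(thi)^2
        if (is.finite(v)) v else 0
      }, numeric(1))
    }, lower = -pi / 2, upper = pi / 2,
    rel.tol = 1e-10, abs.tol = 1e-10, subdivisions = 400L),
    error = function(e) stop(sprintf("oracle quadrature failed: %s",
                                     conditionMessage(e)), call. = FALSE))
  den <- stats::dt(t, nu)
  structure(list(bf10 = num$value / den,
                 quadrature_abs_err = num$abs.error / den),
            class = "oracle_result")
}

#' @export
print.oracle_result <- function(x, ...) {
  cat(sprintf("oracle BF10 = %g (quadrature abs err %.2e)\n",
              x$bf10, x$quadrature_abs_err))
  invisible(x)
}

#' Synthetic two-arm continuous trial
#'
#' Simulates two normal arms with a given standardized mean difference and
#' returns their summary statistics.  Arm 2 has mean 0 and arm 1 mean
#' `delta * sd`, so positive `delta` raises arm 1.
#'
#' @param n1,n2 Arm sizes (>= 2).
#' @param delta True standardized mean difference.
#' @param sd Common true SD of the outcome (default 1).
#' @param seed Integer seed; the output is a deterministic function of it.
#' @return A [trial_summary_continuous()] with per-arm means and SDs.
#' @examples
#' gen_trial_continuous(50, 50, delta = 0.5, seed = 1)
#' @export
gen_trial_continuous <- function(n1, n2, delta, sd = 1, seed) {
  if (n1 < 2 || n2 < 2) stop("arm sizes must be at least 2", call. = FALSE)
  if (sd <= 0) stop("`sd` must be positive", call. = FALSE)
  set.seed(seed)
  y1 <- stats::rnorm(n1, mean = delta * sd, sd = sd)
  y2 <- stats::rnorm(n2, mean = 0, sd = sd)
  trial_summary_continuous(n1, n2, mean(y1), mean(y2),
                           sd1 = stats::sd(y1), sd2 = stats::sd(y2))
}

#' Synthetic two-arm dichotomous trial
#'
#' @param n1,n2 Arm sizes (>= 1).
#' @param p1,p2 True event probabilities, strictly inside (0, 1).
#' @param seed Integer seed.
#' @return A [trial_summary_binomial()].
#' @examples
#' gen_trial_binomial(100, 100, 0.1, 0.12, seed = 7)
#' @export
gen_trial_binomial <- function(n1, n2, p1, p2, seed) {
  if (n1 < 1 || n2 < 1) stop("arm sizes must be at least 1", call. = FALSE)
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1) {
    stop("event probabilities must lie strictly inside (0, 1)", call. = FALSE)
  }
  set.seed(seed)
  trial_summary_binomial(n1, n2,
                         stats::rbinom(1, n1, p1),
                         stats::rbinom(1, n2, p2))
}

#' Sequential Bayes-factor trajectory
#'
#' Simulates a two-arm trial accruing `step` participants per arm at a
#' time and records the two-sided default Bayes factor at each checkpoint.
#' Under a true null the trajectory drifts toward evidence for the null;
#' under a true effect it grows without bound --- the symmetric-stopping
#' property that motivates sequential Bayes-factor monitoring.
#'
#' @param true_delta True standardized mean difference.
#' @param n_max Maximum per-arm sample size.
#' @param step Per-arm accrual between checkpoints (>= 2).
#' @param seed Integer seed.
#' @param prior A [cauchy_prior()] used for every interim look.
#' @return An object of class `"sequential_trajectory"`: data frame with
#'   columns `n_per_arm` and `bf10`, plus attributes `true_delta` and
#'   `seed`.
#' @examples
#' traj <- sequential_bf_trajectory(0, n_max = 100, step = 25, seed = 3)
#' traj$bf10
#' @export
sequential_bf_trajectory <- function(true_delta, n_max, step, seed,
                                     prior = cauchy_prior()) {
  if (step < 2) stop("`step` must be at least 2", call. = FALSE)
  if (n_max < step) stop("`n_max` must be at least `step`", call. = FALSE)
  set.seed(seed)
  y1 <- stats::rnorm(n_max, mean = true_delta)
  y2 <- stats::rnorm(n_max, mean = 0)
  checkpoints <- seq(step, n_max, by = step)
  bf <- vapply(checkpoints, function(n) {
    s <- trial_summary_continuous(n, n, mean(y1[1:n]), mean(y2[1:n]),
                                  sd1 = stats::sd(y1[1:n]),
                                  sd2 = stats::sd(y2[1:n]))
    bf10_eq4(.stat_from_continuous(s), prior)$bf10
  }, numeric(1))
  out <- data.frame(n_per_arm = checkpoints, bf10 = bf)
  attr(out, "true_delta") <- true_delta
  attr(out, "seed") <- seed
  class(out) <- c("sequential_trajectory", "data.frame")
  out
}
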