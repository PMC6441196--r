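test_that("two-sided Bayes factor matches the delta-integration oracle", {
  # independent route: brute-force quadrature over the effect size
  st <- test_statistic(t = 1, df = 18, n_eff = 10)
  pr <- cauchy_prior(0, 1)
  expect_lt(rel_diff(bf10_eq4(st, pr)$bf10, oracle_bf(st, pr)$bf10), 1e-4)
})

test_that("two-sided Bayes factors reproduce the worked reanalyses", {
  bf <- bf10_eq4(stat_adrenaline, default_prior)
  expect_lt(rel_diff(bf$bf10, 0.15), 0.005)
  expect_lt(rel_diff(bf$bf01, 6.64), 0.005)
  expect_lt(rel_diff(bf10_eq4(stat_rbc, default_prior)$bf01, 11.04), 0.005)
})

test_that("bf_value internal consistency: reciprocity and log agreement", {
  for (t in c(-2.3, 0, 0.4, 3.1)) {
    st <- test_statistic(t, df = 40, n_eff = 12)
    for (bf in list(bf10_eq4(st, default_prior),
                    bf_one_sided(st, default_prior, "lower"),
                    bf_interval(st, default_prior, 0.2))) {
      expect_equal(bf$bf10 * bf$bf01, 1, tolerance = 1e-12)
      expect_equal(exp(bf$log_bf10), bf$bf10, tolerance = 1e-12)
    }
  }
})

test_that("zero-centered prior gives an even function of t", {
  for (t in c(0.3, 1.7, 4.2)) {
    for (n in c(8, 120)) {
      st_pos <- test_statistic(t, df = 2 * n - 2, n_eff = n / 2)
      st_neg <- test_statistic(-t, df = 2 * n - 2, n_eff = n / 2)
      expect_equal(bf10_eq4(st_pos, default_prior)$bf10,
                   bf10_eq4(st_neg, default_prior)$bf10,
                   tolerance = 1e-10)
    }
  }
})

test_that("BF10 is nondecreasing in |t| for a zero-centered prior", {
  ts <- seq(0, 6, by = 0.5)
  bfs <- vapply(ts, function(t) {
    bf10_eq4(test_statistic(t, df = 58, n_eff = 15), default_prior)$bf10
  }, numeric(1))
  expect_true(all(diff(bfs) > 0))
})

test_that("one-sided factors decompose the two-sided factor", {
  # with prior halves of exactly 1/2 the one-sided pair averages to BF10
  for (t in c(-1.2, 0.8, 2.5)) {
    st <- test_statistic(t, df = 100, n_eff = 25.5)
    two <- bf10_eq4(st, default_prior)$bf10
    lo <- bf_one_sided(st, default_prior, "lower")$bf10
    up <- bf_one_sided(st, default_prior, "upper")$bf10
    expect_equal((lo + up) / 2, two, tolerance = 1e-8)
  }
})

test_that("one-sided factors reproduce the superiority reanalyses", {
  lo <- bf_one_sided(stat_adrenaline, default_prior, "lower")
  expect_equal(round(lo$bf10, 2), 0.24)
  expect_lt(rel_diff(lo$bf01, 4.23), 0.005)
  # fixed-schedule comparison: trend opposite to the tested direction
  st_sched <- test_statistic((61.3 - 47.6) / ((24.4 - 2.9) / 2 / 1.966),
                             df = 402, n_eff = 203 * 201 / 404)
  expect_lt(rel_diff(bf_one_sided(st_sched, default_prior, "lower")$bf01,
                     31.48), 0.005)
})

test_that("at t = 0 both one-sided factors equal the two-sided factor", {
  st <- test_statistic(0, df = 30, n_eff = 8)
  two <- bf10_eq4(st, default_prior)$bf10
  expect_equal(bf_one_sided(st, default_prior, "lower")$bf10, two,
               tolerance = 1e-8)
  expect_equal(bf_one_sided(st, default_prior, "upper")$bf10, two,
               tolerance = 1e-8)
})

test_that("lower-sided evidence falls below two-sided for positive t", {
  # one- vs two-sided divergence when the data trend against the tested side
  for (t in c(0.5, 1.5, 3)) {
    st <- test_statistic(t, df = 80, n_eff = 20)
    expect_lt(bf_one_sided(st, default_prior, "lower")$bf10,
              bf10_eq4(st, default_prior)$bf10)
  }
})

test_that("interval Bayes factor reproduces the equivalence reanalysis", {
  expect_lt(rel_diff(bf_interval(stat_rbc, default_prior, 0.05)$bf01, 19.09),
            0.005)
})

test_that("interval null converges to the point null as c shrinks", {
  point_bf01 <- bf10_eq4(stat_rbc, default_prior)$bf01
  expect_lt(rel_diff(bf_interval(stat_rbc, default_prior, 1e-4)$bf01,
                     point_bf01), 0.01)
})

test_that("uninformative data give Bayes factors of 1", {
  # in the n_eff -> 0 limit the posterior equals the prior, so every
  # interval (and the point null) is supported exactly as much as before
  # the tail deficit of the posterior against the prior scales like
  # c * sqrt(n_eff), so n_eff must be far below 1/c^2 for the widest c here
  st <- test_statistic(0.01, df = 2, n_eff = 1e-10)
  expect_equal(bf_interval(st, default_prior, 0.3)$bf01, 1, tolerance = 0.01)
  expect_equal(bf_interval(st, default_prior, 100)$bf01, 1, tolerance = 0.01)
  expect_equal(bf10_eq4(st, default_prior)$bf10, 1, tolerance = 0.02)
})

test_that("informative data concentrate all interval evidence inside", {
  # with a sharp posterior near zero, widening the interval only adds
  # support for it; far beyond the posterior spread the complement is empty
  bf05 <- bf_interval(stat_rbc, default_prior, 0.05)$bf01
  bf50 <- bf_interval(stat_rbc, default_prior, 0.5)$bf01
  expect_gt(bf50, bf05)
  expect_error(bf_interval(stat_rbc, default_prior, 100), "no posterior mass")
})

test_that("non-inferiority composite obeys the transitivity identity", {
  st <- test_statistic(-2.1, df = 63, n_eff = 16.2)
  pr <- cauchy_prior(location = 0.22)
  ni <- bf_noninferiority(st, pr)
  comp <- attr(ni, "components")
  expect_equal(ni$bf10, comp$lower$bf10 / comp$upper$bf10, tolerance = 1e-12)
  # swapping the sides inverts the composite exactly
  swapped <- comp$upper$bf10 / comp$lower$bf10
  expect_equal(ni$bf10 * swapped, 1, tolerance = 1e-10)
})

test_that("shifted priors are handled stably on both sides of the null", {
  # mu * t < 0 exercises the cancellation-safe bracket evaluation
  for (t in c(-3.2, -1, 2.5)) {
    for (loc in c(-0.4, 0.25)) {
      st <- test_statistic(t, df = 998, n_eff = 250)
      pr <- cauchy_prior(loc, 0.707)
      expect_lt(rel_diff(bf10_eq4(st, pr)$bf10, oracle_bf(st, pr)$bf10), 1e-4)
    }
  }
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(test_statistic(NaN, 10, 5), "finite")
  expect_error(test_statistic(1, -1, 5), "positive")
  expect_error(test_statistic(1, 10, 0), "positive")
  expect_error(cauchy_prior(scale = 0), "positive")
  expect_error(cauchy_prior(location = Inf), "finite")
  expect_error(bf10_eq4(test_statistic(1, 0.5, 5), default_prior), "df < 1")
  expect_error(bf_interval(stat_rbc, default_prior, -0.1), "positive")
})
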