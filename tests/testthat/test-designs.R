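test_that("superiority workflow reproduces both bronchiolitis reanalyses", {
  rep1 <- analyze_superiority(trials$adrenaline$summary)
  expect_lt(rel_diff(rep1$bayes_factors$lower$bf01, 4.23), 0.005)
  expect_lt(rel_diff(rep1$bayes_factors$two_sided$bf01, 6.64), 0.005)
  expect_lt(rel_diff(rep1$bayes_factors$two_sided$bf10, 0.15), 0.005)
  expect_equal(round(rep1$statistics$t, 2), -0.80)

  rep2 <- analyze_superiority(trials$schedule$summary)
  expect_lt(rel_diff(rep2$bayes_factors$lower$bf01, 31.48), 0.005)
  expect_lt(rel_diff(rep2$bayes_factors$two_sided$bf10, 2.24), 0.005)
})

test_that("equivalence workflow reproduces the red-cell storage reanalysis", {
  rep <- analyze_equivalence(trials$rbc_storage$summary, equiv_c = 0.05)
  expect_equal(round(rep$statistics$t, 2), -0.77)
  expect_lt(rel_diff(rep$bayes_factors$two_sided$bf01, 11.04), 0.005)
  expect_lt(rel_diff(rep$bayes_factors$interval$bf01, 19.09), 0.005)
  # without a margin only the point-null factor is reported
  rep0 <- analyze_equivalence(trials$rbc_storage$summary)
  expect_named(rep0$bayes_factors, "two_sided")
})

test_that("non-inferiority workflow reproduces all three reanalyses", {
  cap <- analyze_noninferiority(trials$cap_macrolide$summary, margin = 0.03)
  expect_equal(round(cap$statistics$std_margin, 2), 0.11)
  expect_equal(round(cap$statistics$t, 2), -3.16)
  expect_lt(rel_diff(cap$bayes_factors$noninferiority$bf10, 1307.76), 0.005)

  flq <- analyze_noninferiority(trials$cap_fluoroquinolone$summary,
                                margin = 0.03)
  expect_lt(rel_diff(flq$bayes_factors$noninferiority$bf10, 39.07), 0.005)

  icbt <- analyze_noninferiority(trials$icbt_post$summary, margin = 2)
  expect_equal(round(icbt$statistics$std_margin, 2), 0.22)
  expect_equal(round(icbt$statistics$t, 2), -2.48)
  expect_lt(rel_diff(icbt$bayes_factors$noninferiority$bf10, 90.52), 0.005)
})

test_that("a vanishing margin degenerates to the superiority one-sided ratio", {
  s <- trials$icbt_post$summary
  ni <- analyze_noninferiority(s, margin = 1e-7)
  sup <- analyze_superiority(trial_summary_continuous(
    s$n1, s$n2, s$m1, s$m2, sd1 = s$sd1, sd2 = s$sd2))
  ratio <- sup$bayes_factors$lower$bf10 / sup$bayes_factors$upper$bf10
  expect_lt(rel_diff(ni$bayes_factors$noninferiority$bf10, ratio), 1e-3)
})

test_that("swapping arm order flips the statistic and the one-sided pair", {
  a <- analyze_superiority(trial_summary_continuous(40, 50, 2.1, 1.4,
                                                    sd1 = 1, sd2 = 1.2))
  b <- analyze_superiority(trial_summary_continuous(50, 40, 1.4, 2.1,
                                                    sd1 = 1.2, sd2 = 1))
  expect_equal(a$statistics$t, -b$statistics$t, tolerance = 1e-12)
  expect_equal(a$bayes_factors$lower$bf10, b$bayes_factors$upper$bf10,
               tolerance = 1e-8)
  expect_equal(a$bayes_factors$two_sided$bf10, b$bayes_factors$two_sided$bf10,
               tolerance = 1e-8)
})

test_that("higher-is-better outcomes mirror onto the canonical frame", {
  # same trial seen on a flipped scale must give the same composite factor
  worse <- analyze_noninferiority(
    trial_summary_continuous(32, 33, 13.6, 17.1, sd1 = 9.8, sd2 = 8),
    margin = 2, higher_is_worse = TRUE)
  better <- analyze_noninferiority(
    trial_summary_continuous(32, 33, -13.6, -17.1, sd1 = 9.8, sd2 = 8),
    margin = 2, higher_is_worse = FALSE)
  expect_equal(worse$bayes_factors$noninferiority$bf10,
               better$bayes_factors$noninferiority$bf10, tolerance = 1e-8)
})

test_that("evidence bands follow the conventional thresholds", {
  expect_identical(classify_bf(11.04), "positive")
  expect_identical(classify_bf(1), "anecdotal")
  expect_identical(classify_bf(2.99), "anecdotal")
  expect_identical(classify_bf(3), "positive")
  expect_identical(classify_bf(39.07), "strong")
  expect_identical(classify_bf(1 / 39.07), "strong")
  expect_identical(classify_bf(1307.76), "overwhelming")
  expect_error(classify_bf(-1), "positive")
})

test_that("design workflows validate their inputs", {
  expect_error(analyze_superiority(trials$cap_macrolide$summary),
               "trial_summary_continuous")
  expect_error(analyze_superiority(trials$adrenaline$summary,
                                   prior = cauchy_prior(0.2)), "zero-centered")
  expect_error(analyze_noninferiority(trials$cap_macrolide$summary,
                                      margin = -0.03), "positive")
  expect_error(analyze_noninferiority(trials$adrenaline$summary, margin = 2),
               "SDs")
})
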