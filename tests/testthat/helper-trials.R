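# Shared fixtures: the worked reanalysis inputs and the statistics they
# imply, used across the unit and acceptance tests.

trials <- example_trials()

stat_adrenaline <- test_statistic(
  t = (63.6 - 68.1) / (11 / 1.966), df = 402, n_eff = 203 * 201 / 404)

stat_rbc <- test_statistic(
  t = (8.516 - 8.683) / (3.6 * sqrt(1 / 538 + 1 / 560)),
  df = 1096, n_eff = 538 * 560 / 1098)

default_prior <- cauchy_prior()

# relative-difference helper for comparisons against 2-decimal printed values
rel_diff <- function(x, ref) abs(x - ref) / abs(ref)
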