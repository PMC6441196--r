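Package: trialbf
Title: Default Bayes Factors for Superiority, Equivalence, and
    Non-Inferiority Trial Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes default (Jeffreys-Zellner-Siow) Bayes factors for
    two-arm clinical trials from summary statistics alone.  Supports
    superiority (point null, one- or two-sided), equivalence (point or
    interval null), and non-inferiority (margin-shifted Cauchy prior)
    designs, for continuous outcomes (means and standard deviations, or a
    reported confidence interval) and dichotomous outcomes (event counts,
    via Cohen's h and the normal approximation).  The marginal likelihood
    under the shifted Cauchy effect-size prior is evaluated by adaptive
    quadrature over the mixing variance in log space, with an independent
    brute-force oracle, synthetic trial generators, and a command-line
    interface included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
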