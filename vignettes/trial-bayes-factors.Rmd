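---
title: "Default Bayes factors for superiority, equivalence, and non-inferiority designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Default Bayes factors for superiority, equivalence, and non-inferiority designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialbf)
```

## The model

A two-arm trial with a continuous outcome reports arm sizes $n_1, n_2$,
means, and either arm SDs or a confidence interval for the difference.
Everything the default Bayes factor needs is captured by three numbers:
the pooled-variance $t$ statistic, its degrees of freedom
$\nu = n_1 + n_2 - 2$, and the effective sample size
$n_\mathrm{eff} = n_1 n_2 / (n_1 + n_2)$, which scales the noncentrality:
given a standardized effect $\delta$ (Cohen's $d$), the statistic follows
a noncentral $t$ distribution with noncentrality
$\delta \sqrt{n_\mathrm{eff}}$.

The null hypothesis fixes $\delta$ at a point (zero, or a standardized
margin); the alternative places a Cauchy prior on $\delta$ with location
$\mu_\delta$ and scale $r$.  The Bayes factor is the ratio of marginal
likelihoods,

$$
BF_{10} \;=\;
\frac{\int f_{\nu,\,\delta\sqrt{n_\mathrm{eff}}}(t)\,
      \mathrm{Cauchy}(\delta;\, \mu_\delta, r)\, d\delta}
     {f_{\nu,\,0}(t)},
$$

with $f_{\nu,a}$ the noncentral-$t$ density.  The Cauchy prior is the
scale mixture of a normal prior on $\delta$ whose variance $g$ follows a
scaled inverse-chi-square distribution with one degree of freedom, so the
same quantity can be written as a one-dimensional integral over $g$ in
which the inner $\delta$ integral is available in closed form (a rescaled
noncentral-$t$ density expressed through the confluent hypergeometric
function $_1F_1$).  `bf10_eq4()` evaluates that mixing-variance integral;
`oracle_bf()` evaluates the $\delta$ integral directly.  The two are
independent numerical representations of the same number and cross-check
each other to $10^{-4}$ relative in the test suite.

Directional and interval hypotheses come from the posterior of $\delta$
(`posterior_delta()`), by mass decomposition:

* one-sided: $BF_{-0} = BF_{10} \cdot
  \Pr(\delta < 0 \mid \mathrm{data}) / \Pr(\delta < 0)$, and analogously
  for the upper side.  With a zero-centered prior the prior halves are
  exactly $1/2$ and the two one-sided factors average to the two-sided
  one.
* interval null $-c < \delta < c$: the ratio of posterior to prior odds
  of the interval.  As $c \to 0$ this converges to the point-null
  Savage-Dickey density ratio; the package switches to that ratio (with a
  warning) if the requested interval is narrow enough to underflow.

Dichotomous outcomes use the normal approximation for a difference of
proportions with a pooled-proportion standard error, and standardize the
margin with Cohen's $h$, the arcsine-square-root transform, anchored at
the pooled event proportion of the two arms.  The resulting $Z$ is
treated as $t$ with $\nu = n_1 + n_2 - 2$; at trial-scale sample sizes
the two are indistinguishable.

## The three designs

**Superiority** tests $\delta = 0$ against a zero-centered alternative;
`analyze_superiority()` reports the two-sided factor and both one-sided
factors, since a pre-specified direction and the two-sided view can
disagree sharply when the observed trend opposes the tested direction.

**Equivalence** reads the same two-sided factor in the other direction:
$BF_{01}$ quantifies support *for* no effect, which is exactly what an
equivalence claim needs and what significance testing cannot provide.  If
a clinically motivated band $(-c, c)$ exists, `analyze_equivalence()`
additionally reports the interval-null factor.

**Non-inferiority** asks whether the new treatment is worse than control
by more than a margin.  The classical statistic is computed against the
margin point; shifting that frame so the margin sits at $\delta = 0$
moves the prior center to the standardized margin $+m$ (the prior is
"centered on no effect" in the original frame).  The quantity of interest
compares the non-inferior side against the inferior side directly, via
transitivity through the margin point:
$BF_{-+} = BF_{-0} \times BF_{0+}$, the ratio of the two one-sided
factors in the shifted frame.  Note that the two-sided factor cancels in
this ratio: $BF_{-+}$ equals the posterior odds of the two sides divided
by the prior odds.

Direction handling is explicit rather than implicit in signs: `margin`
is always positive, and `higher_is_worse` states whether large outcome
values are harmful.  Internally the harmful direction is mapped onto the
positive side (mirroring the statistic when needed), so "non-inferior"
is always the lower side of the shifted frame and the reported $BF_{-+}$
always reads non-inferior over inferior.

## Parameters and defaults

* **Prior scale `r`** (default $\sqrt{2}/2 \approx 0.707$, effect-size
  units).  Jeffreys' original analysis used $r = 1$; the
  $\sqrt{2}/2$ default matches the convention of the widely used
  BayesFactor/JASP implementations, and it is the value under which the
  package's worked examples reproduce their published Bayes factors.
  Larger scales favor the null for the same data (more of the prior mass
  sits at implausibly large effects).  It is exposed everywhere
  (`cauchy_prior(scale = )`, `--prior-scale`) precisely so that
  robustness to this choice can be examined by a parameter sweep.
* **Prior location `location`** (default 0).  Nonzero values encode a
  shifted alternative; `analyze_noninferiority()` sets it to the
  standardized margin internally and rejects user-shifted priors to avoid
  double shifting.
* **Margin** — raw outcome units for continuous outcomes (standardized
  internally by the pooled SD), proportion points for dichotomous ones
  (standardized via Cohen's h).  Positive by construction.
* **Confidence level for `se_from_ci()`** (default 0.95, exact quantile
  1.959964).  Hand calculations in the literature sometimes use slightly
  different multipliers (e.g. 1.966); downstream Bayes factors move well
  under half a percent for such differences.
* **Evidence bands** in reports follow the conventional thresholds
  (1-3 anecdotal, 3-20 positive, 20-150 strong), half-open on the left,
  with values above 150 labelled "overwhelming" as a presentation-only
  extension.  Reports round Bayes factors to 2 decimals for display; JSON
  output retains full precision in a separate key, and all internal
  comparisons use unrounded values.

## Numerical choices

The mixing-variance integrand is evaluated entirely in log space
(`lgamma`, a log-space $_1F_1$ series).  Three details matter:

* The integral over $g \in (0, \infty)$ is transformed to the unit
  interval by $u = g/(1+g)$, probed on a 301-point grid to locate its
  peak, rescaled by the peak value, and integrated adaptively
  (`stats::integrate`, relative tolerance $10^{-8}$).  This keeps the
  computation stable for $|t|$ well beyond 10 and $n$ beyond $10^4$,
  where naive arithmetic overflows.
* The $_1F_1$ bracket of the integrand is a sum of two terms whose signs
  differ when $\mu_\delta t < 0$ (a shifted prior with the statistic on
  the other side — exactly the non-inferiority configuration).  In the
  far tail the two terms cancel catastrophically.  Whenever the log-space
  difference would amplify rounding error by more than $10^3$, the
  bracket is recomputed from an equivalent strictly positive integral
  representation, $\int_0^\infty s^\nu
  e^{-((t^2+\nu)s^2 - 2 a t s + a^2)/2}\, ds$ (the defining chi-scale
  integral of the noncentral-$t$ density), which is log-concave and is
  integrated after rescaling by its analytically known mode.
* Posterior and oracle quadrature over $\delta$ use the substitution
  $\delta = c_0 + w \tan\theta$ with the center at the precision-weighted
  posterior peak.  Two separated scales must stay resolvable in
  $\theta$: the posterior core (width
  $1/\sqrt{n_\mathrm{eff} + r^{-2}}$) and the much larger radius at
  which the likelihood extinguishes the heavy Cauchy tails
  ($\sim (|t|+40)/\sqrt{n_\mathrm{eff}}$); $w$ is their geometric mean.
  Posterior normalization is required to hold to $10^{-6}$ relative and
  errors out otherwise; interval masses below $10^{-12}$ of the total are
  reported as zero rather than chased.

Degenerate inputs (non-finite $t$, $\nu < 1$, non-positive
$n_\mathrm{eff}$ or scale) are rejected with input errors rather than
propagated as NaN.  Very small $n_\mathrm{eff}$ is legitimate and gives
Bayes factors approaching 1 — the uninformative-data limit in which the
posterior equals the prior; in that limit the interval Bayes factor is 1
for *every* half-width.  For informative data, by contrast, widening the
interval only accumulates evidence for it (the posterior's
likelihood-suppressed tails empty the complement), so the interval factor
grows with $c$ rather than returning to 1; the test suite pins down both
regimes.

## What the synthetic generators emulate

`gen_trial_continuous()` and `gen_trial_binomial()` draw ideal
parallel-group trials: normal outcomes with common variance, binomial
events, no dropout, no baseline covariates, no clustering or
heteroscedasticity.  `sequential_bf_trajectory()` accrues such data in
equal per-arm batches and records the two-sided factor at each look,
emulating interim monitoring with a fixed prior.  Passing tests therefore
demonstrate correctness of the computation and its sampling behavior
under the model's own assumptions; they say nothing about robustness to
non-normal outcomes, unequal variances (the package pools; a Welch-style
variant is out of scope), or informative dropout in real trials.

Monte Carlo checks use 20-40 replicates at a few hundred participants
per arm with fixed seeds — enough to separate the medians they compare
by an order of magnitude, and chosen so the full suite runs in seconds.

## Known limitations

* Summary statistics in, Bayes factors out: no patient-level data,
  covariate adjustment, or multi-arm designs.
* Dichotomous outcomes rely on the normal approximation with a
  pooled-proportion SE; very small samples or near-boundary event rates
  deserve an exact treatment the package does not attempt.
* The prior family is the (shifted, scaled) Cauchy only; informed
  non-Cauchy priors are out of scope, though location/scale sweeps cover
  the usual robustness analyses.
* One-sided factors are computed by posterior-mass decomposition rather
  than closed-form truncated-prior expressions; the two agree
  mathematically, and the decomposition is what the oracle can verify.

## A worked example

```{r}
ex <- example_trials()
analyze_noninferiority(ex$icbt_post$summary, margin = 2)
```

The 2-point margin on the depression scale standardizes to $d = 0.22$
via the pooled SD; the statistic against the margin is $t = -2.48$; and
the composite factor $BF_{-+} \approx 90$ says the data are about ninety
times more likely under non-inferiority than under inferiority —
"strong" on the conventional scale, despite only 65 participants.
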