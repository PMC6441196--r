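# trialbf

Default Bayes factors for two-arm clinical trials, computed from summary
statistics alone.

Superiority, equivalence, and non-inferiority designs all hinge on a null
hypothesis, but significance tests can only ever reject one — they cannot
quantify support *for* it.  That is exactly what an equivalence claim
("the treatments do not differ") or a non-inferiority claim ("the new
treatment is not worse by more than the margin") needs.  `trialbf` is for
trialists, meta-researchers, and reviewers who want to reanalyze reported
trial results on the evidence scale that can do this: the Bayes factor.

## The model

For a two-arm comparison summarized by a pooled-variance statistic
*t* with *ν* = *n*₁ + *n*₂ − 2 degrees of freedom and effective sample
size *n*ₑ = *n*₁*n*₂/(*n*₁ + *n*₂), the default (Jeffreys–Zellner–Siow)
Bayes factor compares a point null for the standardized effect δ against
a Cauchy-prior alternative:

    BF₁₀ = ∫ f(t; ν, δ√nₑ) Cauchy(δ; μ_δ, r) dδ  /  f(t; ν, 0)

where *f*(·; ν, a) is the noncentral-t density, μ_δ the prior center and
*r* the prior scale (default √2/2).  The package evaluates this as a
log-space adaptive quadrature over the normal-prior mixing variance (the
Cauchy is a scaled inverse-chi-square mixture of normals), and
cross-checks it against an independent brute-force integration over δ.

One-sided hypotheses use posterior-mass decomposition
(BF₋₀ = BF₁₀ · P(δ<0 | data)/P(δ<0)); interval nulls −c < δ < c use the
posterior-to-prior odds of the interval; non-inferiority margins are
standardized (Cohen's d via the pooled SD, Cohen's h for proportions),
the statistic is taken against the margin point, the prior is recentered
at the standardized margin, and the composite factor follows by
transitivity: BF₋₊ = BF₋₀ × BF₀₊.

## A worked example

The bronchiolitis trial of Skjerven et al. (2013, NEJM) compared racemic
adrenaline against saline inhalation on length of hospital stay (hours):
203 vs 201 infants, means 63.6 vs 68.1, 95% CI of the difference
(−6.5, 15.5).  A superiority reanalysis from exactly these numbers:

```r
library(trialbf)
adren <- trial_summary_continuous(203, 201, 63.6, 68.1,
                                  se_diff = se_from_ci(-6.5, 15.5))
analyze_superiority(adren)
#> Bayesian superiority analysis (two-arm trial)
#>   prior: Cauchy(location = 0, scale = 0.707107)
#>   statistic: t = -0.8018, df = 402, n_eff = 101.00
#>   BF10 (two-sided)                         0.15   (reciprocal 6.65)
#>   BF-0 (lower one-sided)                   0.24   (reciprocal 4.24)
#>   BF+0 (upper one-sided)                   0.06   (reciprocal 15.44)
#>   evidence: positive
```

The trial's non-significant p = .42 could mean "no effect" or "not
enough data"; the Bayes factor distinguishes them: the null is about 4
times more likely than one-sided superiority of adrenaline (BF₀₋ ≈ 4.2),
positive — but not strong — evidence of no benefit.

Equivalence works the same way, reading the two-sided factor in favor of
the null, optionally with an interval null:

```r
rbc <- trial_summary_continuous(538, 560, 8.516, 8.683, sd1 = 3.6, sd2 = 3.6)
analyze_equivalence(rbc, equiv_c = 0.05)
#> Bayesian equivalence analysis (two-arm trial)
#>   prior: Cauchy(location = 0, scale = 0.707107)
#>   statistic: t = -0.7684, df = 1096, n_eff = 274.39
#>   BF10 (two-sided)                         0.09   (reciprocal 11.05)
#>   BF01 (interval null)                    19.09   (reciprocal 0.05)
#>   evidence: positive
```

and non-inferiority takes a margin plus the direction of harm:

```r
cap <- trial_summary_binomial(656, 739, 59, 82)   # 90-day mortality
analyze_noninferiority(cap, margin = 0.03, higher_is_worse = TRUE)
#> ...
#>   BF-+ (non-inferior vs inferior)       1307.72   (reciprocal 0.00)
#>   evidence: overwhelming
```

`example_trials()` ships all six worked comparisons with their design
settings and provenance.

## Command line

A thin wrapper over the same functions is installed at
`inst/cli/trialbf`:

```sh
trialbf superiority --ci-mar 11 --n1 203 --n2 201 --m1 63.6 --m2 68.1
trialbf noninferiority --n1 656 --n2 739 --k1 59 --k2 82 \
        --ni-mar 0.03 --format json
```

Subcommands `superiority`, `equivalence`, `noninferiority`; `--format
json` emits a schema-stable report (full precision and 2-decimal
presentation values side by side); `--config file.json` supplies flags
from a flat JSON document, with explicit flags taking precedence.

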