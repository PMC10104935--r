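---
title: "Severity, specificity, and the evidential value of a design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Severity, specificity, and the evidential value of a design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sevbf)
```

A test is severe when it had a real chance of exposing the hypothesis as
false. This package quantifies that idea in two traditions — the
error-statistical SEV function and Bayesian measures built on the prior
predictive distribution — and supplies the simulation machinery to assess a
planned Bayes-factor experiment before any data exist. This vignette
explains each model, its assumptions, and the numerical and design choices
behind the implementation.

## Error-statistical severity

The setting is a one-sided test of a normal mean with known standard
deviation: `H0: mu <= mu0` against `mu > mu0`, sample size `n`, standard
error `se = sigma / sqrt(n)`. The test rejects when the sample mean clears
`mu0 + z_(1-alpha) * se` (`rejection_threshold()`); with `mu0 = 150`,
`sigma = 10`, `n = 100`, `alpha = 0.025` the cutoff is 151.96, often quoted
rounded to 152. After a rejection, the severity of the further claim
`C: mu >= mu1` given an observed mean `xbar` is

$$\mathrm{SEV} = P(\bar X \le \bar x \mid \mu = \mu_1),
  \qquad \bar X \sim N(\mu_1, se^2),$$

the probability the test would have produced a result no larger than the
one observed were the claim just false. The boundary point `mu = mu1` is
used because it is the value in `C` hardest to distinguish from the null
side; severity against any `mu > mu1` is only higher.

```{r sev}
spec <- normal_test_spec(mu0 = 150, sigma = 10, n = 100, alpha = 0.025)
sev(spec, mu1 = 153, xbar = 152)
```

Two structural facts are worth internalizing (both are asserted as
properties in the test suite). First, `SEV = 0.5` exactly when the claim
threshold equals the observed mean. Second, SEV depends only on `mu1`,
`xbar`, and the standard error — not on `mu0`. A laboratory whose normal
state is 100 and one whose normal state is 150 compute the *same* severity
for the claim `mu >= 153` from the same observed mean of 152, even though
the observations are fifty-two standard errors apart in surprisingness.
Whether that invariance is a feature or a defect of SEV as an evidence
measure is exactly the kind of question the Bayesian quantities below are
designed to answer; the package computes both so the contrast can be made
concrete.

Only the one-sided-greater direction is implemented. The `direction` field
exists in the spec object so that a lesser or two-sided extension would be
additive rather than a signature change. Unknown-sigma (t-based) severity
is out of scope.

## Interval hypotheses under an encompassing prior

The Bayesian half of the package works with two independent binomial
success rates — two treatments, `theta_A` and `theta_B` — and hypotheses
that restrict each rate to a closed interval, e.g.

* vague: `H_v: theta_A in [0, 0.5], theta_B in [0.5, 1]` (prior mass 0.25),
* specific: `H_s: theta_A in [0.2, 0.3], theta_B in [0.7, 0.8]` (mass 0.01),

both nested in the encompassing model `H_e = [0,1] x [0,1]` with
independent uniform (Beta(1,1)) priors. A constrained hypothesis inherits
the truncated uniform prior. The Bayes factor of a constrained hypothesis
against `H_e` then has a closed form: the ratio of posterior to prior mass
of its region,

$$\mathrm{BF} = \frac{P(\theta \in R \mid y)}{P(\theta \in R)},$$

where each arm's posterior is `Beta(s + 1, n - s + 1)`. All region
probabilities are computed as regularized incomplete-beta CDF differences —
no quadrature, no Monte Carlo — so the worked scenarios are exact to
floating point. The package nevertheless computes the two marginal
likelihoods independently inside `bf_vs_encompassing()` and refuses to
return if the two routes disagree beyond 1e-6 relative tolerance; the test
suite additionally checks both against adaptive-quadrature and Monte-Carlo
oracles. The ratio is capped at one over the prior region mass: a
hypothesis occupying 1% of the encompassing model can earn at most a Bayes
factor of 100, which is how specificity buys evidential potential.

```{r bf}
h_s <- interval_hypothesis(c(0.2, 0.3), c(0.7, 0.8), "H_s")
d20 <- binomial_design(20, 20)
bf_vs_encompassing(h_s, binomial_outcome(5, 15, d20))
```

Point (zero-length) hypotheses are rejected: their prior mass is zero and
the mass-ratio construction degenerates. Only box constraints are
supported; order constraints (`theta_B > theta_A`) and non-uniform
encompassing priors are out of scope. The machinery is written for the
two-arm case; the product-of-arms formulas would extend to more arms, but
no such surface is exposed.

## Prior predictives and the HDR plausibility check

What a hypothesis predicts is its prior predictive distribution: per arm,

$$p(S = s \mid H) = \int_{lo}^{hi}
  \binom{n}{s}\theta^s(1-\theta)^{n-s}\,
  \frac{d\theta}{hi - lo},$$

again an incomplete-beta difference (the binomial coefficient cancels
against the beta normalizer, leaving `1/(n+1)` times the CDF difference
over the interval length). `hdr_complement()` turns this into a severity
precondition: the highest-density region at coverage `1 - epsilon` is the
smallest set of support points, taken in decreasing probability order,
whose mass reaches the coverage, and outcomes outside it are the ones the
hypothesis effectively forbids. A hypothesis that forbids no plausible
outcome cannot be tested severely no matter what data arrive.

Two numerical choices matter here. Tied probabilities at the inclusion
boundary enter the HDR together, so the region is well-defined on flat
stretches of pmf (for one observation under a uniform prior, a 50% HDR is
the whole support `{0, 1}`). And the rule is greedy-minimal: the test suite
verifies both that the region holds the coverage and that removing its
least probable member (with its ties) would break it. On discrete, possibly
multimodal pmfs this set-based HDR can be non-contiguous — for the specific
hypothesis at `n = 20` the 99% complement of arm A is `{0} ∪ {11..20}`,
with the boundary points `S = 0` (mass 0.00413) and `S = 11` (mass 0.00407)
both just outside. Boundary outcomes that close to the coverage knife-edge
should not be over-interpreted either way.

## Expected evidential value of a design

Before the experiment, the strength of evidence it will deliver — in either
direction — is a random variable. The package's pre-experimental severity
measure is its expectation under the mixture marginal of the two models
being compared:

$$\mathbb{E}_y\!\left[\,|\log \mathrm{BF}(y)|\,\right]
 = \sum_y p(y)\,\bigl|\log \mathrm{BF}(y)\bigr|,
 \qquad p(y) = w_H\, p(y \mid H) + w_e\, p(y \mid H_e).$$

The outcome space is the finite `(n_A + 1) x (n_B + 1)` lattice, so the sum
is exact — there is no quadrature or simulation error to manage. Three
conventions are fixed by `expected_abs_log_bf()` and validated by the
worked scenarios:

* **natural logarithm** (nats), the standard choice in the
  expected-information literature;
* **equal model weights** `(0.5, 0.5)` by default, a configurable
  parameter;
* `|log BF|` evaluated in log space from log marginal likelihoods, never by
  exponentiating and re-logging, so lattice corners whose Bayes factor
  underflows to zero still contribute finite terms.

Under these defaults the four design scenarios give 6.32 (specific, n=20),
3.14 (vague, n=20), 1.61 (specific, n=4), and 1.25 (vague, n=4): the
specific hypothesis with the small sample still promises more expected
evidence than — comparable machinery shows — vagueness can extract from a
sample five times larger. Jensen's inequality
(`expectation >= |signed mean|`) holds by construction and is asserted on
randomized scenarios.

`empirical_content()` carries the same idea into pure prediction counting:
a theory that allows rain on exactly 3 unspecified days of 30 is consistent
with `choose(30, 3) = 4060` of the `2^30` binary sequences, while naming
the three days leaves exactly 1. Counts use closed forms where available
(they are integer-exact in doubles far beyond these sizes); arbitrary
predicates are counted by enumeration, which is refused beyond 25 slots.

## Bayes Factor Design Analysis

For a two-sample comparison the package simulates the planned experiment:
draw `n` observations per group from `N(0, 1)` and `N(d, 1)` (unit
variance, the effect injected as a mean shift), form the pooled-variance t
statistic, and convert it to a JZS Bayes factor — H1 places a Cauchy prior
with scale `r` on the standardized effect, H0 pins it at zero, and the
numerator marginal likelihood is a one-dimensional adaptive quadrature of
the noncentral-t likelihood against the prior. The integration substitutes
`delta = r * u` so the integrand keeps a fixed scale for any `r`; the test
suite checks the result against an independent fixed-grid trapezoid oracle
and verifies the limits (BF below 1 at `t = 0`, BF tending to 1 as
`r -> 0`).

Each simulated Bayes factor is classified against evidence thresholds
`(L, U)`, by default `(1/3, 3)`: above `U` is evidence for H1, below `L`
evidence for H0 — *misleading* evidence when the generating effect is real
— and the band between is inconclusive. The three rates sum to one, carry
binomial Monte-Carlo standard errors, and are bit-reproducible under a
seed.

```{r bfda, eval = FALSE}
simulate_bfda(bfda_spec(n_per_group = 36, effect_size_d = 0.4,
                        n_sims = 10000, seed = 1))
#> BFDA: n = 36/group, d = 0.4, r = 0.7071, thresholds (3, 0.3333), 10000 sims
#>   evidence for H1 (BF > 3):       35.4% (se 0.48 pp)
#>   inconclusive:                   54.5% (se 0.50 pp)
#>   evidence for H0 (BF < 0.333):   10.1% (se 0.30 pp)
```

One calibration decision deserves emphasis. The `alternative` argument of
`jzs_bf10()` and `bfda_spec()` chooses between the symmetric Cauchy prior
(`"two.sided"`) and the half-Cauchy on positive effects (`"greater"`). The
default is `"greater"`: with `n = 36`, `d = 0.4`, `r = sqrt(2)/2` the
directional analysis yields approximately 9.6% misleading and 55%
inconclusive evidence, the operating characteristics this design is known
for from the interactive BFDA planning app; the symmetric prior roughly
doubles the misleading rate (to about 20%), because half its prior mass
sits on effects of the wrong sign and negative sample effects then read as
evidence *for* that half. Sensitivity to the prior scale under the
directional default, from 10,000-replicate runs of `simulate_bfda()`:
`r = 0.5` gives about 4.8% misleading / 57% inconclusive,
`r = sqrt(2)/2` about 9.5% / 55%, `r = 1` about 15.5% / 52%. A larger prior
scale makes H1 more audacious and hence easier to mislead against when the
true effect is moderate.

The classification boundaries are open intervals (a Bayes factor exactly at
a threshold counts as inconclusive) — immaterial in practice since the BF
is continuous. Only fixed-n designs are implemented; sequential designs,
one-sample and paired layouts are out of scope.

### What the simulation does and does not emulate

The generator draws exactly the data-generating process the design analysis
assumes: independent normal observations with unit variance and a pure mean
shift. Real two-group data bring unequal variances, non-normality, and
dependence, none of which the rates account for; a passing design analysis
certifies the *design* under its stated model, not robustness to model
violation. Default problem sizes were chosen as the smallest that make the
Monte-Carlo error negligible relative to the quantities of interest:
10,000 replicates put a binomial standard error of about 0.3 percentage
points on a 10% rate, and the unit-test tier uses a few hundred replicates
where only structural properties (summation, seeding, monotonicity) are at
stake.

## Scenarios and the command line

Every worked example ships as a YAML scenario under
`system.file("scenarios", package = "sevbf")`, runnable with
`run_scenario(load_scenario(path))` or from a shell via the wrapper
`system.file("cli", "sevbf.R", package = "sevbf")` (subcommands `sev`,
`bf`, `evidential-value`, `bfda`, `run`; JSON to stdout or `--output`;
exit code 2 on configuration errors, 3 on numerical errors). Scenario
loading rejects unknown keys by name, and seeds are always part of the
scenario, so stochastic results rerun identically. One YAML caveat: an
unquoted key `n:` is a boolean in YAML 1.1, so the bundled files quote it
and the loader maps the stray boolean back defensively.

## Known limitations

* SEV covers only the known-sigma, one-sided normal-mean test.
* Interval hypotheses are boxes over two arms; no order constraints, no
  non-uniform encompassing priors, no multinomial extension.
* The discrete HDR is computed on per-arm marginals, not the joint
  lattice; a joint HDR would differ when arms are strongly asymmetric.
* BFDA rates are Monte-Carlo estimates; at the default 10,000 replicates,
  rates near 50% carry a standard error of half a percentage point.
* The expected-evidential-value lattice enumeration is quadratic in the
  per-arm sample size; it is instantaneous for n in the tens and remains
  comfortable into the thousands, but is not intended for very large n.
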