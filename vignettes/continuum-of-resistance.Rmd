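---
title: "Non-response bias under the continuum of resistance: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-response bias under the continuum of resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corsurvey)
```

## The problem and the estimator

House-to-house health surveys lose roughly four in ten sampled adults to
unit non-response, and the people lost are not a random subset: heavier
drinkers are widely believed to be harder to contact and less willing to
take part. Interview weights correct the demographic profile of the
respondents, but they cannot correct for behaviour that differs *within*
demographic cells.

The continuum of resistance model offers a way to probe the residual bias
using fielding paradata. It assumes that sample members lie on a single
continuum of resistance to being interviewed; participants who required
many contact attempts sit near the non-participant end, so non-participants
are taken to resemble the hardest-to-contact participants. Operationally,
with participants split into an easy group (1–6 contact attempts, about
80%) and a hard group (7+), a measure with survey-weighted participant
estimate $p$, hard-group estimate $h$ and individual response proportion
$r$ is adjusted to

$$p_{\mathrm{adj}} \;=\; p\,r \;+\; h\,(1-r).$$

`cor_adjust()` implements exactly this mixture; it is linear in $r$,
bounded between its two arguments, and applied unchanged to prevalences
and to means. The package computes it for seven headline alcohol measures
per sex (`cor_table()`), alongside the descriptive and regression analyses
that motivate it.

Because the contact-attempts paradata of the real survey this emulates are
not publicly releasable, the package pairs the analysis code with a
synthetic data generator calibrated to the published margins, so every
estimator can be validated against a known truth.

## The fielding simulator

Each sampled adult gets demographics drawn from independent marginals
(sex, three age bands, economic activity, income and deprivation
quintiles, nine regions, survey year) and a latent resistance score

$$R_i = \lambda_{\mathrm{age}} + \lambda_{\mathrm{econ}} +
        \lambda_{\mathrm{region}} + \varepsilon_i,\qquad
  \varepsilon_i \sim N(0, \sigma^2_R),$$

with loadings chosen so that young, in-work and London-resident adults are
the most resistant, matching the published demographic gradients of the
7+ group. Response has two stages, separating refusal from non-contact:

1. **Willingness**: ever-cooperating is Bernoulli with probability
   $\operatorname{logit}^{-1}(a_w - b_w R_i)$.
2. **Contact**: a willing person is reached on attempt $k$ with probability
   $\operatorname{logit}^{-1}\!\big(a_c - b_c R_i + f(k)\big)$, the first
   success is recorded as the number of attempts, and fieldwork stops
   after 18 attempts (anyone not reached is a non-respondent).

$f(k)$ is a piecewise-linear effect of the attempt number (slopes for
attempts up to 6, 7–8, and beyond 8). A constant per-attempt probability —
i.e. geometric waiting times — cannot reproduce the published attempt
distribution: conditioning a (mixed) truncated geometric on mean 4.44
forces an SD of at least 3.58, about 22.6% of interviews beyond 6 attempts
and only 86.5% within 8, all far outside the published 2.84, 18.8% and
90%. Substantively, a rising-then-varying hazard is also what call-record
studies describe: once a household has been identified, later calls are
often appointments rather than cold calls. The attempt effect is therefore
part of the model, not a nuisance fix.

### Calibration

The five fielding parameters $(a_w, b_w, a_c, b_c)$ and the three slopes
of $f$ were fitted once by Nelder–Mead against five moments — response
rate 58%, mean attempts 4.44, SD 2.84, interview-weighted 7+ share 18.8%,
share within 8 attempts 90% — computed *deterministically* by enumerating
the demographic cells and integrating the resistance noise with
Gauss–Hermite quadrature (no simulation noise in the objective). The
optimum reproduces all five moments to four decimals and is frozen in
`default_config()`; a 2-million-person simulation confirms it (58.02%,
4.444, 2.841, 18.86%, 89.97%). The default sample size of 44,303 makes
58% response yield about 25,700 interviews over the three survey years.

The weighted and unweighted 7+ shares differ slightly (the weights
up-weight hard-to-reach cells); the packaged calibration pins the
*weighted* share at 18.8%, matching how the published table is weighted.

Interview weights are cell-based inverse response propensities over sex ×
age band × region, rescaled to mean 1 over participants
(`compute_weights()`); a cell with sampled adults but no participants has
its age band collapsed toward the middle band in a fixed order before
weighting. This mimics what a non-response weight does at cell level and
is deliberately not any agency's production weighting algorithm.

The sampled-population marginals are set to the published *participant*
composition; the true frame composition is unpublished, and the
approximation affects only how far the weights have to travel, not any
calibrated quantity.

## The drinking model

Drinking is generated per sex, conditional on demographics and on the
person's **contact stratum**: hard (7+ attempts) for hard-to-contact
participants *and* for non-participants, easy otherwise. Assigning
non-participants the hard stratum is precisely the continuum-of-resistance
assumption, so the generator's default world is one in which the model
holds; a configuration knob (`nonparticipant_extra_logodds`) breaks it on
purpose for misspecification studies. True values for everyone, including
non-participants, are kept in a truth table attached to the dataset;
the analytic export blanks all drinking fields of non-respondents.

Five nested binary outcomes — drinks nowadays ⊇ drank last week ⊇
exceeded the daily guideline ⊇ heavy episodic, and weekly-guideline
exceedance ⊆ drinks nowadays — each follow a logistic model
$\operatorname{logit} P = \alpha + x'\beta_{\mathrm{demo}} +
\beta_G\,\mathrm{hard}$. A single latent uniform per person drives the
nested chain (a person's indicators are the uniform compared with the four
ordered probabilities), which guarantees logical consistency *and* keeps
every marginal exactly logistic, so the conditional odds ratios
$e^{\beta_G}$ are known by construction. The hard-group effects are set to
the published fully-adjusted odds ratios (women: 1.19 daily, 1.23 heavy
episodic; men: 1.14 drinks-nowadays, 1.12, 1.10, 1.09), and the
demographic coefficients give young, in-work adults the heaviest episodic
drinking — which is what makes the *unadjusted* group contrasts larger
than the conditional ones, as in the published regression table.
Configuration validation enforces the probability ordering across the
whole covariate grid, so an inconsistent model is rejected before any
data are drawn.

Continuous variables are drawn consistently with the indicators:
heaviest-day units fall in the band the indicators dictate (below the
daily threshold, between daily and heavy thresholds, or threshold plus a
Gamma tail), weekly units likewise around the weekly limit, drinking days
are 1 + a beta-binomial on 0–6 for last-week drinkers (dispersion 1.4
reproduces the published SD of about 2 days), and non-drinkers are zero on
everything. Intercepts were solved by root-finding so the
interview-weighted hard-group marginals hit the published 7+ column
(e.g. heavy episodic 24.3% men, 17.2% women) on a 2-million-person
fielding; the easy-group and whole-sample margins then fall out close to
their published counterparts without being targeted. One published cell is
internally inconsistent (the men's daily-guideline 7+ percentages are
transposed against their own counts); the calibration uses the
count-implied 43.1%.

Item non-response is missing-completely-at-random (1% per drinking item,
15% for income), enough to exercise the per-variable complete-case
machinery without biasing anything.

## Estimation conventions

* **Weighted proportion / mean / SD** use the plain weighted formulas
  (`sum(w x)/sum(w)`; population-style SD). With integer weights they
  equal the unweighted statistics on the row-replicated data — the oracle
  the tests use.
* **Chi-squared**: Pearson statistic on the weighted contingency table
  after rescaling weights to sum to the unweighted n; with equal weights
  this is the classical test. The original analysis was run in a
  statistics package whose exact weighted-test variant is not documented;
  this convention keeps type-I error near nominal at unit weights.
* **t-tests**: Welch, with each group's effective sample size
  $(\sum w)^2 / \sum w^2$ (Kish) in place of n; reduces exactly to
  `t.test()` at unit weights.
* **Logistic regressions** are weighted ML fits with weights rescaled to
  mean 1 (so the weight scale cannot shrink or inflate model-based
  standard errors; unit-weight fits are exactly classical), Wald 95%
  intervals $\widehat{OR}\cdot e^{\pm z_{.975}\,SE}$, complete cases only,
  reference level the easy group. Age enters as the three bands the data
  are generated in. With a lone binary predictor the fitted OR equals the
  2×2 cross-product ratio (tested to 1e-8).
* $r$ defaults to the overall individual response proportion
  (participants / sampled adults); a per-sex $r$ is accepted since the
  source analysis does not say which it used. All differences and percent
  changes are computed from unrounded intermediates and rounded only in
  the formatted output layer.
* Guideline comparisons read "more than" strictly: exactly 4/3, 8/6 or
  21/14 units does **not** exceed. The source derivation's boundary
  handling is unstated; strictness is this package's documented choice,
  and thresholds are overridable (e.g. the post-2016 14/14 weekly
  guideline) for sensitivity runs.

## Validity simulations: what passing shows

Two properties anchor the adjustment:

1. **Unbiasedness under exchangeability.** The estimator is unbiased when
   non-participants' outcomes are distributed like the hard group's. In
   the default configuration that is *almost* true — both share the
   hard-stratum drinking model — but their covariate mixes differ (the
   most resistant people are the most demographically skewed), leaving a
   small composition bias. The validity test therefore zeroes the
   resistance loadings, making response independent of demographics; the
   two distributions are then exactly equal, and the adjusted
   heavy-episodic prevalence matches the truth-table population value
   within Monte-Carlo error (10 runs at n = 100,000).
2. **Graceful failure.** When non-participants drink strictly more than
   the hard group (extra +0.5 log-odds), the adjusted estimate remains
   biased low but is strictly closer to the truth than the weighted
   estimate — the adjustment attenuates, and cannot overshoot, this form
   of misspecification.

What the synthetic data do **not** emulate: household clustering and
design effects (each adult is sampled independently), interviewer effects,
informative item non-response, under-reporting of consumption relative to
sales, year trends, and 16–17-year-olds. Passing tests therefore show the
estimators and the adjustment behave correctly under the stated sampling
model — not that real-survey non-response is fully captured by a single
latent resistance factor.

## Numerical and testing choices

Determinism: one top-level seed is split into fixed per-stage sub-seeds
(population, fielding, drinking, missingness), so identical configuration
and seed give byte-identical datasets and pipeline outputs. Logistic fits
use a convergence epsilon of 1e-12 so closed-form comparisons hold to
1e-8; fits are flagged (not errored) on non-convergence or likely
separation. Degenerate inputs — empty strata, single observations, empty
contact groups, zero-variance t-tests, degenerate contingency tables —
either error with the offending column/row named or return `NA` columns,
as documented per function.

Problem sizes in the test-suite were chosen to keep the full run around
15 seconds while leaving every check well-powered: five full-size
(n = 44,303) replicates for the calibration and recovery checks, ten runs
at n = 100,000 for the validity simulation, four replicates at n = 8,000
for null-effect recovery (where the check is that ~95% Wald intervals
cover OR 1; the test bound of 85% over 96 intervals allows for simulation
noise), and n of a few thousand for structural tests. The recovery check
compares the across-seed mean log-OR with the generator's value within
twice its Monte-Carlo standard error, computed from the per-fit Wald
standard errors (a far more stable estimate of the same sampling
variability than an SD over five replicates).

## Known limitations

The single-factor resistance model makes refusal and non-contact
perfectly correlated through $R$; surveys distinguish them, and the split
of attempts before vs after first contact is a modelling choice here, not
a published quantity. The weighted 7+ share, not the unweighted one, is
calibrated; the published table does not say which of its N columns are
weighted. And the adjustment itself inherits the model's central
assumption — if non-participants differ from the hardest-to-contact
participants in ways the hard group does not reveal, `cor_adjust()`
moves estimates in the right direction but cannot recover the truth, as
the misspecification simulation demonstrates.
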