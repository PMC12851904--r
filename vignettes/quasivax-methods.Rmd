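---
title: "Methods: threshold-based quasi-experiments for vaccination rollouts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold-based quasi-experiments for vaccination rollouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quasivax)
```

## The design

`quasivax` analyses vaccination programmes that were rolled out with a strict
date-of-birth eligibility threshold, as natural experiments for later health
outcomes. The motivating setting is the Welsh herpes-zoster rollout: people
who turned 80 just before the programme start date (born on or before
1933-09-01) never became eligible, while those born on or after 1933-09-02
were offered the vaccine in a staggered catch-up schedule. People born weeks
apart are alike in everything that varies smoothly with age, but differ
sharply in their probability of ever being vaccinated, so the jump in an
outcome at the threshold identifies a causal effect of eligibility, and the
ratio of that jump to the uptake jump identifies the effect of vaccination
among compliers. This avoids the healthy-vaccinee bias that afflicts
associational comparisons of recipients with non-recipients.

The package implements the full analysis surface around that idea:

* a **sharp regression discontinuity** (RD) for intent-to-treat (ITT)
  effects: the outcome is regressed on eligibility, the centred week of
  birth, and their interaction, within a bandwidth and under triangular
  kernel weights;
* a **fuzzy RD** for the complier average causal effect (CACE): receipt is
  instrumented by eligibility, sharing the sharp fit's bandwidth and
  weights, so the point estimate is exactly the ITT divided by the
  first-stage uptake jump;
* a **birth-season difference-in-differences** (DID) triangulation with a
  testable parallel-trends assumption;
* gender-interaction instrumental-variable models, severity-score subgroup
  splits and delta-method relative effects;
* a falsification suite: placebo thresholds, pre-period outcomes, baseline
  balance, negative-control outcomes and robustness grids;
* a synthetic linked-EHR cohort generator that provides ground truth for all
  of the above.

## Running variable and the straddling week

Linked demographic registers carry dates of birth at week resolution, weeks
starting on a Monday. The running variable is the signed number of weeks
between the week of birth and the threshold: 0 is the first eligible week.
The week containing the threshold date belongs wholly to neither side. The
default rule assigns it to the side holding the majority of its seven days;
for the 1933-09-02 threshold (a Saturday) that week holds only two eligible
days and therefore joins the ineligible side. The rule is configurable
(`eligible`, `ineligible`, `drop`) because the assignment is a genuine
convention, and its sensitivity is testable.

The synthetic generator defines eligibility at the same week resolution, so
that the analysis invariant "eligible if and only if the centred week of
birth is non-negative" holds exactly and the configured uptake jump is the
estimand of the first stage. This mirrors the fact that the analyst of the
real data observes only the week of birth.

## Estimation and inference

Within a bandwidth $h$, each side of the threshold is fit by weighted
least squares of order $p$ (default local linear; local quadratic available,
higher orders deliberately not offered) with triangular weights
$K(u) = \max(0, 1-|u|)$. Both the conventional jump estimate and every other
boundary quantity are *linear functionals of the outcome*, represented
internally by explicit weight vectors. This makes three things exact by
construction:

* the sharp estimate equals the closed-form weighted least-squares solution;
* the fuzzy estimate times the first-stage jump equals the ITT whenever the
  two fits share bandwidth and weights (the Wald identity);
* delta-method variances of ratios (fuzzy effects, relative effects) are
  sandwich variances of composed influence vectors.

**Bias correction.** A local fit of order $p$ at bandwidth $h$ carries a
leading smoothing bias proportional to the $(p+1)$-th derivative of the
conditional mean at the boundary. The package estimates that derivative with
an order-$q = p+1$ fit at a (generally wider) bias bandwidth $b$, subtracts
the implied bias from the point estimate, and widens the variance by the
sampling variability of the bias estimate: the combined estimator is again a
single linear functional, so the "robust bias-corrected" standard error is
its sandwich variance. The robust interval is centred on the bias-corrected
estimate and need not contain the conventional one. For fuzzy designs the
delta method is applied to the bias-corrected numerator and denominator with
their full covariance.

**Variance estimators.** The running variable is discrete (weekly mass
points), so the default sandwich clusters on week of birth, which is the
conservative choice; a plain heteroskedasticity-robust estimator is
available. A nearest-neighbour residual variance is not offered: with
hundreds of persons per mass point it degenerates into a within-week
estimate that the cluster estimator already dominates.

**Bandwidth selection.** The main bandwidth minimises the asymptotic mean
squared error of the boundary jump estimator:
$h \propto \left(\frac{C_v\,(\sigma_L^2+\sigma_R^2)/f_0}
{2(p+1)\,C_b^2\,\bar B^2}\right)^{1/(2p+3)} n^{-1/(2p+3)}$,
with closed-form triangular-kernel constants $C_b, C_v$, boundary variances
and running-variable density estimated in a pilot window
($1.84\,\mathrm{sd}(x)\,n^{-1/5}$), and the curvature contrast $\bar B$
taken from one-sided global polynomial fits (the Taylor coefficient of
$s^{p+1}$, estimated from an order-$(p+2)$ fit). $\bar B^2$ is regularised
by the pilot's own sampling variance so near-zero curvature yields a wide
but finite bandwidth rather than a degenerate one; fully degenerate pilots
fall back to the rule-of-thumb bandwidth with a warning. The bias bandwidth
$b$ solves the analogous problem for the curvature estimand (rate
$n^{-1/(2q+3)}$) and is floored at $h$. Ties at $|x| = h$ are included in
the estimation sample; the triangular weight there is zero, so the choice is
inert but documented for bit-reproducibility.

**Covariates and fixed effects.** Additive adjustment with coefficients
common to both sides: the covariate coefficients are estimated in the
kernel-weighted within-bandwidth regression and partialled out of the
outcome before the univariate machinery runs. Fixed-effect factors (e.g.
rollout cohort under the staggered index-date policy) expand to indicators;
levels without support inside the kernel window are dropped as
uninformative. The small additional variance from estimating the covariate
coefficients is not propagated, matching common practice for linear
covariate adjustment in this design.

## Follow-up windows, outcomes and the staggered rollout

Outcomes are nine-year cumulative binary indicators by default, ascertained
in `[index + grace, index + follow_up)`. The grace period shortens time at
risk without moving the calendar end of the window. The
"MCI not followed by dementia within K months" robustness outcomes use
30.44-day months by default (a calendar-month rule is configurable) because
month arithmetic is otherwise undefined for these data. Under the staggered index-date policy, eligible persons index at their
own eligibility date; never-eligible persons inherit the index date of
their mirror image across the threshold (born $k$ weeks before maps to $k$
weeks after), which preserves age-at-index comparability, and analyses add
rollout-cohort fixed effects.

## The birth-season difference-in-differences

Persons born 1926-03-01 to 1934-02-28 are divided into yearly cohorts
centred on September 1 and into pre-September (March-August) and
post-September (September-February) birth seasons; February 29 births fall
in the post season by these date ranges. Eligibility differs between
seasons only in the 1933/34 cohort, so a linear probability model of the
outcome on the season-by-1933/34 interaction with birth-month and cohort
fixed effects identifies the ITT analogue, and two-stage least squares with
that interaction as the excluded instrument identifies the receipt effect.
The identifying assumption — equal between-season gaps across cohorts absent
the programme — is testable: the pretest estimates every cohort's season gap
against the 1932/33 reference and flags any significant non-1933/34 gap.
The pipeline reports the flag but does not hard-block estimation for
outcomes that fail it; the flag is the analyst's go/no-go. Standard errors
are heteroskedasticity-robust by default (the equations are linear in a
binary outcome).

## Severity scores and relative effects

Dementia severity at baseline is proxied by five measures: dementia-related
inpatient days, dementia-related admissions, dementia diagnosis recordings,
and two model-based risks — death due to dementia and death from any cause
over nine years — from logistic models on age at programme start and the
Charlson comorbidity conditions (the condition catalogue used here has 16
conditions; AIDS is never a predictor), the dementia-death model adding the
care-intensity counts. Coefficients are estimated on ineligible persons
only, and predictions impute a fixed age of 80 so the score never reads a
person's true age (which would leak the running variable into the
subgrouping). Separated likelihoods refit with a small ridge penalty and a
warning. Subgroups split at the median of the full scored cohort (a configurable
choice; whether the median should be taken inside or outside the bandwidth
is genuinely open, and the full-cohort median is the more stable quantity),
with ties assigned below.

Relative effects divide the absolute effect by the predicted outcome level
just left of the threshold: the ITT denominator is the left intercept of the
sharp fit; the receipt denominator is the untreated-complier left limit,
computed under one-sided noncompliance as (left limit of $Y$ minus right
limit of $Y(1-V)$) divided by the first-stage jump. Numerator and
denominator are linear functionals of the data, so the delta-method interval
uses their full covariance. Dementia-type contrasts report relative point
estimates only — there is no established interval method for relative
effects in this design — and default to women, where the heterogeneity
analyses locate the effect.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, not
the clinical richness of real records. Defaults are calibrated once to the
study conditions: dates of birth uniform over September 1925 - September
1942; uptake 0 left of the threshold and 0.459 (0.287 among persons living
with dementia at baseline) at the threshold; baseline cognitive-impairment
and dementia prevalences reproducing the printed cohort shares (92.7% /
4.7%); nine-year outcome risks of 7.3% (MCI at the threshold age) and 49.1%
(death due to dementia); a female share of 54.6%; primary-care visit rates
of 2 per year, which reproduce the printed 48% share of frequent attenders;
and true ITT effects of -1.5 (MCI) and -8.5 (dementia deaths) percentage
points, acting *only through receipt*, so the true CACE equals the ITT
divided by the uptake jump by construction. Outcome risk is linear in age on
the log-odds scale (about a doubling per six years; quadratic curvature
configurable) — identification requires only continuity, and log-odds
linearity makes local-linear recovery clean while remaining mildly curved on
the probability scale. Event times are uniform within the follow-up window
given occurrence, which supports variable follow-up windows with exact
monotone nesting. The default gender effect ratio is 1 (homogeneous);
heterogeneity analyses are exercised with explicit non-unit ratios.

Every person carries potential-outcome bookkeeping (event probabilities and
both potential outcomes per outcome, compliance class), exposed as a
`truth` attribute, so tests can verify that the realised outcome equals
`Y(receipt)` and that the mean complier effect equals the configured CACE to
machine precision.

Deliberate simplifications, hence what passing tests do and do not show:
one risk draw per outcome rather than longitudinal hazards; no registration
delay on death dates; diagnosis dates clamped at the death date rather than
jointly modelled; a dementia-caused death event always contributes the
underlying cause (so the configured risk and effect are exact for the
ascertained outcome); comorbidities independent across conditions;
no coding-system richness (single dementia code in place of full code
lists); and pre-period events independent of everything else. Passing the
suite shows the estimators are correct under the assumed structure — smooth
age trends, a clean uptake discontinuity, quasi-random assignment near the
threshold — not that any real rollout satisfies those assumptions.

## Numerical choices and degenerate inputs

* Estimation needs more distinct running-variable values than the
  polynomial order on each side, else an error names the side.
* A first-stage jump below 0.01 (configurable) aborts fuzzy estimation with
  a weak-instrument error; the DID analogue requires a first-stage F of at
  least 10.
* Relative effects error when the denominator is within a guard of zero;
  pre-period tests with no events return an exact zero with a
  degenerate-variance warning.
* Constant covariates in the balance suite are skipped with a note; failing
  robustness-grid or placebo cells are marked failed without aborting the
  run.
* No multiple-testing correction anywhere in the falsification suite,
  matching the design's framing; expected-by-chance counts are printed
  alongside.

## Problem sizes used in the shipped tests

The simulation-based checks run at cohort size 60,000 with 500 replicates
for recovery and coverage of the primary estimator (plus 150 null
replicates), 20 replicates for placebo rejection rates, 5 replicate suites
of the 36 balance tests, and a 2,000-draw bootstrap against the
delta-method interval on a 6,000-person cohort. These sizes put
Monte-Carlo error comfortably below the tolerances asserted while keeping
the suite runnable on a laptop.

## Known limitations

* Covariate adjustment is additive only; the fully nonparametric
  covariate-balancing RD variant is out of scope.
* No survival or competing-risk modelling: outcomes are cumulative
  incidence binaries, as in the design this package operationalises.
* The bias-corrected interval's finite-sample coverage depends on the
  plug-in bandwidths; the shipped coverage simulations exercise the default
  configuration only.
* The DID estimator is the simple two-cohort-design 2SLS; no event-time or
  staggered-adoption generalisations.
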