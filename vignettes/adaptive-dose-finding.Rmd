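---
title: "Adaptive dose-finding on a dose-inefficacy curve: model, designs and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive dose-finding on a dose-inefficacy curve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmineff)
```

## The problem

Phase-I dose-finding for an antiretroviral (a long-acting peptide fusion
inhibitor given by single subcutaneous injection) differs from the oncology
setting in which the continual reassessment method (CRM) grew up. The
steering endpoint is not toxicity but *inefficacy*: a participant's response
is 1 if their drug concentration fails to stay a fixed multiple above the
IC50 out to the furthest sampling time, 0 otherwise. The probability of
inefficacy is assumed to decrease monotonically with dose, so the trial
explores the *right-hand tail* of the curve: the interesting region is where
inefficacy becomes rare, because the dose carried into the multiple-dosing
stage should work for essentially everyone. The tolerable inefficacy rate
for that dose was set at 5%, and the **target dose** of a true curve is the
dose with the highest inefficacy probability at or below 5% — on a monotone
curve, the lowest qualifying dose (`derive_target_dose()`).

Two competing designs are implemented, both dosing 20 active participants:

* **Fixed "5+5+5+5" benchmark** — five participants at each of 10, 20, 40
  and 80 mg, no adaptation, rule-based final selection.
* **Three-period hybrid adaptive design** — period 1 doses two participants
  at each of 10/20/40/80 mg (a rule-based escalation/safety phase that also
  guards the CRM against early unexpected outcomes); period 2 allocates 10
  participants in cohorts of two by CRM, refitting the model before every
  cohort; period 3 optionally doses the final two participants at the
  selected dose to enrich PK information. Cohorts of two balance estimation
  accuracy against the turnaround delay of the PK endpoint.

## The model

Responses are Bernoulli with a one-parameter logistic dose-inefficacy
curve,

$$\operatorname{logit}(p_i) = 5 - \beta d_i, \qquad \beta > 0,$$

where $d_i$ is the standardised dose. The intercept is fixed at 5 so that
the probability of inefficacy with no drug is `plogis(5)` ≈ 0.993 — an
untreated participant essentially cannot reach an effective concentration.
One-parameter models estimate poorly far from the data but are adequate
around the target dose, which is all the design needs. Restricting
$\beta > 0$ encodes monotonicity.

Standardised doses come from *backward fitting*: a dose anticipated to have
inefficacy probability $p$ maps to $5 - \operatorname{logit}(p)$
(`backward_fit_standardised_dose()`). Applied to the anticipated curves,
this shows that dividing the actual doses (mg) by 10 puts the 10–80 mg grid
on a sensible scale, which is the default `dose_grid()` mapping.

### Posterior updating by quadrature

The posterior over $\beta$ is one-dimensional, so the package computes it
by deterministic quadrature instead of MCMC: 4001 midpoint nodes on
$(0, 10]$, masses proportional to prior times Bernoulli likelihood,
accumulated in log space with max-subtraction (`posterior_update()`). This
removes Monte-Carlo noise from every design decision — the same data always
produce the same next cohort — and is orders of magnitude faster than
sampling. Quantiles of $\beta$ (median, credible limits) are read off a
monotone cubic interpolation of the midpoint-corrected CDF, so they vary
smoothly rather than snapping to grid points; doubling the resolution moves
the posterior median and every per-dose estimate by well under $10^{-4}$.
The upper support bound 10 is far beyond any plausible slope: at
$\beta = 10$ even 10 mg has inefficacy probability below 0.01. Credible
intervals for per-dose probabilities are the monotone image of the central
$\beta$ interval. A history whose likelihood underflows everywhere raises
an explicit numerical-failure error rather than returning nonsense.

### The prior

The original design description says only that the prior on $\beta$ was
*vague*, with prior 90% bands at most doses covering essentially the whole
probability range. The default here is $\beta \sim \mathrm{Uniform}(0,10)$
on the discretised support, which reproduces exactly that behaviour (the
prior bands at 10–50 mg span ≈ [0, 1]); an exponential prior (rate 0.2) is
available as a second diffuse family, and `til_sensitivity()` tabulates how
much the headline operating characteristics move across priors and decision
rules. They move by a few percentage points — which is also the honest
uncertainty to attach to any comparison against the originally published
adaptive-design numbers, since the original prior is unknown.

### Point-estimate conventions

Two per-dose summaries are always stored: the plug-in curve at the
posterior median of $\beta$ (the construction used for plotting fitted
curves) and the posterior mean of each $p_d$. The *active* convention,
driving both the next-cohort rule and model-based selection, is the
posterior mean. This choice is deliberate: the published example
realisations show the cohort after an all-ineffective 10/20 mg escalation
going to 50 mg, and to 40 mg when 20 mg had one effective response; under
the uniform prior the posterior-mean convention reproduces both decisions,
while the median plug-in chooses one dose lower in each case (the median
curve is systematically steeper than the posterior-averaged curve early in
the trial, when the posterior on $\beta$ is heavily right-skewed). The
switch is `model_spec(estimate = )`.

## Decision rules

* **Next cohort** (`choose_next_dose()`): the dose whose estimated
  inefficacy probability is *closest to* the target inefficacy level (TIL)
  — closest rather than below, because the adaptive phase should straddle
  the region of interest. Ties break toward the higher dose (selecting too
  low a dose is considered worse than too high). An alternative
  interval-probability rule (maximise posterior mass of $p_d$ within TIL ±
  0.025) is available behind `design_spec(decision_rule = "interval")`; if
  no dose carries any mass in the band it falls back to the closest rule.
  Dose skipping is permitted — the published example realisations jump to
  doses never previously given.
* **Final selection**, computed on period 1–2 data only:
  * *rule-based* (`select_dose_rule_based()`): lowest administered dose
    with no failures at it or at any higher administered dose;
  * *model-based* (`select_dose_model_based()`): lowest grid dose with
    estimated inefficacy probability strictly below the TIL.
* **Period 3**, when enabled, doses the model-selected dose; if the
  model-based criterion selects nothing, period 3 is skipped. Its responses
  feed back into nothing. The default is `period3 = FALSE`, matching the
  published operating-characteristic tables, whose adaptive allocation
  rows sum to 18 participants.

## Scenarios

The evaluation bank (`scenario_bank()`) holds seven true curves. Scenario 1
is specified exactly (0.95, 0.75, 0.40, 0.05, 0.04, 0.03, 0.02, 0.01 at
10–80 mg; target 40 mg). The other six were published only in summary form
(target dose, shape class), so the bank *emulates* them parametrically —
logistic curves anchored so the target rule returns the documented target
(60 mg; 80 mg at the upper boundary; none; all doses effective), a shallow
logistic (slope 0.6 vs ≈ 2 for the likely scenarios), and a reverse-J curve
that copies Scenario 1 up to 40 mg and then rises. Every emulated scenario
is tagged `emulated = TRUE`, and quantitative comparisons against published
tables are made for Scenario 1 only; for the emulated scenarios the
package's results characterise the *method*, not the original report.

The scenario grid is always the full 8-dose grid even though period 1 and
the fixed design use only four of them — mid-grid doses like 30 mg can be
both allocated and selected by the adaptive design.

## Simulation and evaluation

`simulate_design()` generates independent realisations from one master
seed expanded into per-realisation substream seeds (results do not depend
on evaluation order), and averages: selection probabilities per criterion,
allocation per dose, ineffective-response counts, and participants dosed
below target (reported as `NA` when the scenario has no target).
`fixed_design_oracle()` computes the fixed design's distribution *exactly*:
the rule-based criterion depends on the data only through the four
zero-failure indicators, whose joint distribution factorises into
$(1-p_d)^5$ terms — 16 events, no simulation. The stochastic engine is
required (by test) to agree with this enumeration to Monte-Carlo accuracy,
which pins down the whole realisation/selection pipeline independently of
the random-number path.

Summary measures condense a selection distribution relative to the target
dose: SM1 (target or higher), SM2 (target or one level higher), SM3
(target exactly), SM4 (target or one level either side), and a weighted
measure
$p(d_t) + \sum_{i=t+1}^{\min(8, t+4)} p(d_i)(1 - (i-t)/5) - 2\,p(\text{no
dose})$ that discounts selections above target linearly and penalises
selecting nothing. The printed source for this formula gives the summation
limit as $\max(8, t_d+4)$, which contradicts its own worked example
(target index 6, terms up to dose index 8); the implementation uses
$\min(8, t_d+4)$, consistent with the example. When no target exists every
measure collapses to the probability of correctly selecting no dose.
`design_difference()` reports adaptive-minus-benchmark per measure,
positive favouring the adaptive design.

## Problem sizes and reproducibility

The package's own evaluation runs use 1000 realisations per cell — the
scale of the original comparison — which takes well under a minute per
adaptive cell with the quadrature engine. `repeat_stability()` quantifies
the Monte-Carlo spread of the summary measures across repeated
1000-realisation runs; for the fixed design the spread stays within 0.05,
matching the stability reported for the original study. Unit and property
tests run at smaller sizes (tens to a few thousand realisations) chosen to
keep the full suite in the low minutes; the enumeration oracle, not sheer
replication, carries the exactness burden.

## Limitations

* The adaptive design's published operating characteristics depend on the
  original (unpublished) prior and the exact posterior-probability decision
  rule; agreement beyond a few percentage points for those cells is not
  claimed, and `til_sensitivity()` makes the dependence visible.
* Scenarios 2–7 are emulations; their published tables are not
  reproducible from the main-text information.
* The binary endpoint abstracts away the PK analysis that defines it
  (day-4 vs day-7 sampling, IC50 multiples), safety monitoring and
  stopping, placebo participants, and the multiple-dosing stage — none of
  which affect the single-dose design comparison simulated here.
* The simulator draws each participant's response immediately; real
  cohorts respond with delay, which the cohort-of-two structure
  accommodates but the simulation does not model explicitly.
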