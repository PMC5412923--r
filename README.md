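# crmineff

Simulation toolkit for phase-I dose-finding trials that steer on a binary
**inefficacy** endpoint instead of toxicity. It was built for the design
work of a single-dose antiretroviral study (a long-acting peptide fusion
inhibitor), where the question is not "how much drug can we tolerate?" but
"what is the lowest dose that almost never fails to reach an effective
concentration?" — the trial explores the right-hand tail of a monotonically
*decreasing* dose-response curve.

## The model and the designs

Each participant's response is Bernoulli, `y = 1` if the drug concentration
fails to stay 10× above the IC50 out to the furthest sampling time. The
probability of inefficacy at standardised dose *d* (actual dose in mg
divided by 10) follows a one-parameter logistic curve

```
logit(p) = 5 − β d,   β > 0,
```

with the intercept fixed so that inefficacy is near-certain with no drug.
A diffuse prior on β (default Uniform(0, 10)) is updated after every cohort
by deterministic grid quadrature — the posterior is one-dimensional, so no
MCMC is needed and every design decision is exactly reproducible.

Two designs with 20 active participants are compared:

* the fixed **"5+5+5+5"** benchmark: five participants at each of
  10/20/40/80 mg, rule-based selection (lowest administered dose with no
  failures at it or any higher administered dose);
* a three-period **hybrid adaptive design**: 2 × 4 escalation participants,
  then 10 participants in CRM-guided cohorts of two assigned to the dose
  whose estimated inefficacy probability is closest to a target inefficacy
  level (TIL: 5%, 10% or 20%), then an optional two-participant
  confirmation cohort; final selection by the rule-based criterion and/or
  the model-based one (lowest dose with estimated inefficacy below the
  TIL).

Operating characteristics (selection probabilities, allocation, ineffective
counts, participants dosed below target) are averaged over simulated
realisations; the fixed design additionally has an exact enumeration
oracle. Summary measures SM1–SM4 and a weighted summary measure condense
each selection distribution relative to the scenario's target dose (the
dose with the highest true inefficacy probability ≤ 5%).

## Worked example

```r
library(crmineff)

## the printed benchmark scenario: target dose 40 mg
oc <- simulate_design(fixed_design(), scenario1(),
                      n_realisations = 1000, seed = 1)
oc
#> Operating characteristics: 5+5+5+5 under Scenario 1: standard PK model, 40 mg effective
#>   1000 realisations (seed 1); target dose 40 mg
#> N per dose:
#> 10 20 30 40 50 60 70 80
#>  5  5  0  5  0  0  0  5
#> P(selection):
#>      none 10 20 30   40 50 60 70   80
#> rule 0.04  0  0  0 0.74  0  0  0 0.22
#> N ineffective: 8.80   N below target: 10.00
```

The benchmark selects the 40 mg target about 74% of the time, overshoots
to 80 mg 22% of the time, and wrongly abandons the drug about 4% of the
time; it always doses 10 participants below the target. Summary measures
condense this (SM1 = P(target or higher) = 0.96, SM3 = P(target) = 0.74,
weighted measure 0.70).

The adaptive machinery is just as direct. After an escalation phase with
ineffective responses at 10 and 20 mg and effective ones at 40 and 80 mg:

```r
h <- trial_history(1:8, rep(1, 8), rep(c(10, 20, 40, 80), each = 2),
                   c(1, 1, 1, 1, 0, 0, 0, 0))
post <- posterior_update(h)
post
#> CRM posterior from 8 response(s); beta median 1.891 (uniform prior)
#>  dose_mg p_median  p_mean ci_lo ci_hi
#>       10 0.957272 0.95010 0.898 0.978
#>       20 0.771796 0.72213 0.345 0.930
#>       30 0.337987 0.36750 0.030 0.799
#>       40 0.071555 0.14585 0.002 0.544
#>       50 0.011500 0.05301 0.000 0.263
#>       60 0.001753 0.01917 0.000 0.097
#>       70 0.000265 0.00714 0.000 0.031
#>       80 0.000040 0.00278 0.000 0.010
choose_next_dose(post, til = 0.05)
#> [1] 50
```

The next cohort goes to 50 mg — the dose whose estimated inefficacy
probability (5.3%) is closest to the 5% TIL — even though 50 mg has never
been given. A full comparison experiment (all designs × the seven-scenario
bank, with CSV/JSON tables and comparison plots) is one call:

```r
exp <- run_experiment(run_config(n_realisations = 1000, seed = 1),
                      out_dir = "results")
oc_table(exp, "scenario1")
```

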