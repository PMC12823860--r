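---
title: "Model structure, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokeCUA)
```

## The decision problem

Intravenous alteplase given 4.5–24 h after onset of posterior circulation
ischemic stroke improves the 3-month distribution of disability (modified
Rankin Scale, mRS 0–6) relative to standard medical therapy, at the price
of the drug and a higher risk of symptomatic intracranial hemorrhage
(sICH). Whether that trade is worth paying for is a lifetime question: mRS
states differ in annual care cost, quality of life, recurrence risk and
mortality. `strokeCUA` answers it with the standard hybrid structure of
stroke health-economic models: a short decision tree covering the trial's
3-month follow-up window, feeding a Markov cohort model for the remaining
lifetime.

## Decision-tree phase (one quarter)

Each arm's 3-month mRS distribution is taken directly from two-arm trial
data and becomes the cohort's state at the end of the quarter. Three
simplifications, chosen deliberately:

* Patients dead at 3 months are credited 0 life-years and 0 QALYs for the
  quarter, but their acute hospitalization cost is incurred. The trial
  distribution gives status at 3 months, not death times; crediting
  half-quarters would pretend to information we do not have, and the
  simplification is symmetric across arms.
* sICH enters as a one-time management cost and a one-time utility
  decrement (`d_sich × 0.25` QALYs). Its mortality is *not* modelled
  separately: deaths from sICH are already inside the trial's 3-month mRS 6
  proportion, and counting them again would double-count.
* Nothing in the tree is discounted; the whole quarter is treated as time
  zero. At 5%/yr the error over one quarter is below 1.3% of that
  quarter's payoffs, and cycle alignment stays simple.

## Markov phase

States are mRS 0–5 (alive) and Dead. A 30-year horizon at 3-month cycles
means one decision-tree quarter plus **119 Markov cycles** — the cohort
enters at age 64 and exits at 94. (One could also read "30 years" as 120
Markov cycles after the tree; we fix the convention that the tree quarter
is part of the horizon, so the totals cover exactly 30 years.)

Within each cycle events happen in a fixed order:

1. **Background death.** Annual life-table mortality in 5-year bands from
   age 60 (0.00760/yr) to 85+ (0.15120/yr), converted to a quarterly
   probability on the hazard scale and multiplied by an mRS-specific death
   hazard ratio (1, 1, 1.11, 1.27, 1.71, 2.37 for mRS 0–5) and a global
   post-stroke excess hazard ratio (default 1; its plausible excess is
   folded into the mRS 0/1 HR range 1–1.2). Ages beyond the last band keep
   the 85+ rate; the model never needs ages below the first band, but they
   clamp to it.
2. **Recurrent stroke** among survivors, from annual probabilities that
   increase with mRS. A recurrence is fatal with case fatality 0.21;
   survivors remain in their state with probability 0.5, otherwise move
   exactly one mRS level worse, capped at mRS 5. The one-level shift is
   the minimal rule consistent with "same or worse"; both the stay
   probability and the recurrence probabilities are configurable.
3. **Payoffs.** Occupancy is valued with a trapezoidal half-cycle
   correction (the mean of start- and end-of-cycle occupancy), state
   utilities for QALYs and group-level annual care costs (mRS 0–1 vs
   mRS 2–5, divided by 4 per quarter) for costs. Recurrence survivors are
   valued at the recurrence utility 0.42 *instead of* their destination
   state's utility for the event cycle, at full weight; each recurrence
   (fatal or not) incurs the recurrent-stroke event cost. All increments
   in cycle *k* are discounted by `(1 + r)^(-0.25 k)` with r = 5%/yr
   (swept 0–8% in sensitivity analysis); life-years are discounted like
   QALYs and costs.

No tunnel states track recurrence history: a second recurrence is
implicitly allowed, which matches the memoryless reading of the state
diagram.

## Parameters

All parameters live in one YAML file
(`system.file("extdata", "default_model.yaml", package = "strokeCUA")`),
each as a `{value, low, high, source}` block. The `source` tag separates
two classes:

* **PAPER** — printed in the source publication chain: the two arms' mRS
  distributions with their 95% ranges, sICH incidences (0.0172 vs 0.0087),
  death HRs, life table, utilities (0.95, 0.89, 0.67, 0.44, 0.16, 0.10,
  0; recurrence 0.42; sICH disutility 0.38), case fatality 0.21, drug
  prices, discount rate, GDP threshold 95,749 CNY.
* **ASSUMED** — required by the model but not printed anywhere we can cite
  with a number, so packaged as explicit, overridable assumptions: annual
  recurrence 0.02/0.04/0.06 for mRS 0–1/2–3/4–5 (monotone in disability,
  at magnitudes typical of secondary-prevention cohorts); acute
  hospitalization 15–55k CNY rising with mRS (20k for in-hospital deaths);
  annual care 8,000 CNY (mRS 0–1) vs 40,000 CNY (mRS 2–5); recurrence
  event 30,000 CNY; sICH event 20,000 CNY; ±25–50% ranges on these; ±10%
  ranges on utilities. These defaults are *assumptions, not
  reconstructions* — anyone with better local data should override them,
  and the tornado table shows exactly how much they matter.

A consequence worth stating plainly: with the packaged ASSUMED care costs,
the intervention is dominant (cost-saving), so the base-case ICER is
negative and the decision conclusion ("highly cost-effective" at the
1× GDP threshold) does not hinge on the exact assumed values — the one-way
sweeps keep the ICER far below the threshold across every listed range.
The printed totals of the analysis this package models used unpublished
cost inputs and sit in the positive-ICER quadrant; reproducing their exact
magnitudes is not possible from printed information alone.

One printed quirk: the standard arm's seven mRS proportions sum to 1.0001
as published. The loader renormalizes sums within 1e-3 of 1 (and rejects
anything worse), so the packaged file keeps the printed digits verbatim.

## Sensitivity analysis

**One-way (tornado).** Every parameter with a range is set to each bound
with everything else at base case, and the ICER recorded. Sweeping one
component of an mRS distribution would break the simplex, so the varied
component is fixed at its bound and the other six are rescaled
proportionally — tornado rows for mRS components should be read with that
renormalization in mind. Setting any parameter to its base value
reproduces the base-case ICER to 1e-9 relative tolerance (tested).

**Probabilistic.** Each draw samples all parameters jointly and
independently across blocks: whole mRS distributions from a Dirichlet
(concentration 115, the granularity scale of the trial arms — independent
per-component betas would break the sum-to-1 constraint, so the Dirichlet
is a deliberate multivariate generalization of the "beta for
probabilities" rule); scalar probabilities and utilities from
moment-matched betas; costs from moment-matched gammas; death hazard
ratios — which are not bounded in [0, 1], so a beta cannot represent
them — also from moment-matched gammas. Moment matching reads every range
as a symmetric Wald-style 95% interval: SD = (high − low)/3.92; beta
variances are truncated just below the binomial bound m(1−m) when a range
is implausibly wide; zero-width ranges degrade to fixed-value samplers.
Exact CI matching is not attempted. The default is 1,000 iterations under
a recorded seed; the CEAC evaluates, on a 0–120,000 CNY/QALY grid in
1,000-CNY steps (covering both GDP thresholds), the fraction of draws in
which the intervention has the higher net monetary benefit.

Boundary conventions: an ICER exactly at a threshold is assigned to the
middle ("cost-effective") band; dominance overrides thresholds; the
southwest quadrant (cheaper, less effective) is reported but never
auto-classified. The death-HR range for mRS 2 (0.89–1.3) crosses 1 and is
used as printed — we do not truncate it at 1 in sweeps.

## Validation design

The cohort engine's exact expectation is an individual-level process, so
the package ships a microsimulation with the identical event ordering and
payoff rules as an independent oracle: cohort totals must sit within 3
Monte-Carlo standard errors of microsimulated means (2×10⁵ patients per
check, 5 randomized parameter bundles, fixed seeds). This is a strong
whole-engine test — during development it exposed a vectorization bug in
the probability conversion that single-path unit tests missed. Occupancy
conservation (sum 1 within 1e-9 every cycle), Dead-state monotonicity,
discount monotonicity, first-order stochastic dominance of the initial
distribution, and ICER shift/scale invariances are property-tested across
100 randomized bundles.

## Synthetic trials and what they show

`generate_trial_bundle()` emulates the *sampling structure* of a two-arm
trial read off at 3 months: multinomial mRS counts and binomial sICH
counts at configurable arm sizes (default 115, the resolution of the
observed proportions), Wald-style observed ranges, optional gamma noise
(CV 0.2) on costs and beta noise on utilities. `recovery_experiment()`
replicates this end-to-end: at 200 replicates of 115-patient arms the
truth-run ICER falls inside the replicates' 2.5–97.5 percentile band
(tested). What this does **not** show: anything about real-world
transferability — the generator draws from the model's own families, so
recovery checks internal consistency and sampling-noise propagation, not
structural correctness against real registry data.

## Problem sizes and numerical choices

Test and analysis sizes are chosen so the full suite illustrates every
property at meaningful precision: 10⁵ draws for sampler-mean checks (3-SE
criterion), 2×10⁵ individuals per microsimulation comparison, 100 bundles
for conservation properties, 200 recovery replicates, 1,000 PSA
iterations. All randomness flows from explicit integer seeds; identical
seeds give byte-identical outputs (tested at the file level for the CLI).
YAML round-trips write numerics at 17 significant digits so
`load(write(load(f)))` is a bit-exact fixed point.

## Known limitations

* Recurrence and long-term cost inputs are assumptions (flagged), not
  estimates; the absolute ΔC and the sign of the ICER move with them.
* Uniform recurrence case fatality across states; no second-recurrence
  memory; no time-varying treatment effects.
* PSA samples blocks independently — no correlation between, say, utilities
  and care costs.
* The model is a cohort expectation: it produces no patient-level
  variability statements beyond what the microsimulation oracle provides
  internally.
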