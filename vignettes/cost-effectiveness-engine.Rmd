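---
title: "A Markov cohort engine for early cost-effectiveness assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort engine for early cost-effectiveness assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovcea)
```

## The model

Many health and care innovations — falls-prevention programmes,
telemonitoring, integrated-care pathways — are assessed early, with sparse
evidence, across very different populations. A deliberately generic
state-transition model makes such assessments comparable: the cohort
occupies one of three mutually exclusive states, **baseline health**
(the target population's usual health, resource use and mortality),
**deteriorated health** (the condition the intervention aims to prevent
or cure), and **death**. Four transitions connect them:

1. incidence of the deteriorated condition,
2. recovery back to baseline health,
3. baseline mortality (usually age-dependent, from a life table),
4. mortality in the deteriorated state, expressed as an *excess* over
   baseline mortality.

The engine itself is N-state (any number of states with exactly one
absorbing death state); `three_state_spec()` builds the canonical model
above. Each cycle the occupancy row vector is multiplied by a
row-stochastic transition matrix; self-transitions are the row residual
after all exits, and a negative residual (competing exits exceeding 1) is
a hard error rather than a silent renormalisation, because renormalising
would mask invalid inputs.

An intervention is evaluated as two arms — standard care and
intervention — that may differ in any transition, utility or cost.
Per-arm discounted outcomes accumulate over the trace:

$$E = \sum_{t \ge 1} (1+r_E)^{-t\,\ell}\; (\pi_t \cdot u)\, \ell,
\qquad
C = \sum_{t \ge 1} (1+r_C)^{-t\,\ell}\; (\pi_t \cdot c)\, \ell,$$

with $\pi_t$ the occupancy row at cycle $t$, $u$ the per-state utility
weights, $c$ the per-state annual costs, and $\ell$ the cycle length in
years. The incremental summaries are the standard decision metrics:
$\Delta E$, $\Delta C$ (including the discounted intervention delivery
cost), $\mathrm{ICER} = \Delta C / \Delta E$, and
$\mathrm{INMB} = \Delta E \cdot \lambda - \Delta C$ with $\lambda$ the
willingness to pay per QALY. The ICER is reported only in the two
trade-off quadrants of the cost-effectiveness plane; under dominance a
ratio is not meaningful and the dominance class is reported instead.

## Excess mortality: the composition rule

Evidence rarely reports the deteriorated state's absolute death
probability; it reports an *excess* over background mortality, on one of
several scales. The package supports three composition rules, selected
per transition:

* **additive hazards** (`excess_rate`, the default): the background
  death probability is converted to a rate, the excess rate added, and
  the sum converted back with $p = 1 - e^{-r\ell}$. Added hazards always
  yield valid probabilities and compose cleanly with age-dependent
  background mortality, which is why this is the default;
* **hazard ratio** (`excess_rate_ratio`): the background rate is
  multiplied by the ratio;
* **additive probabilities** (`excess_prob`): provided because some
  sources report excess risk directly on the probability scale; the sum
  is range-checked.

## Tunable parameters and their defaults

| Parameter | Default | Why |
|---|---|---|
| cycle length | 1 year | life tables are annual; evidence is typically annualised |
| time horizon | per analysis (`horizon_cycles`) | must reflect the condition; fixtures use 15–25 cycles |
| discount rates (effects, costs) | 3 %/yr each, separately configurable | jurisdictions differ in both level and whether the rates are equal |
| half-cycle correction | on | transitions happen throughout a cycle; counting membership at cycle end overstates occupancy changes. Implemented as the trapezoid average of adjacent occupancy rows; switch off to match closed-form hand calculations |
| $\lambda$ | 30 000 per QALY | common European reference range; always report the CEAC rather than a single threshold |
| perspective | societal | these interventions shift costs across budget holders; healthcare-payer view is one switch away |
| utility bounds | $[0, 1]$ | the conventional utility scale (0 = death, 1 = full health); set `c(-1, 1)` where the EQ-5D value set admits states worse than dead. Out-of-bounds state utilities are errors, not clamps — except utilities produced by instrument mapping, which are clamped and logged, since a published mapping can legitimately predict slightly outside the scale |

Rewards accrue from cycle 1 (cycle 0 is the known starting state;
accruing it would double-count the start under both arms). The
intervention delivery cost has a one-off component at cycle 0
(undiscounted) and a per-cycle component discounted at the cost rate.

## Uncertainty analysis

Parameter uncertainty is described per parameter by a distribution —
conventionally beta for probabilities and utilities, gamma for costs and
rates, lognormal for hazard ratios — parameterised either naturally or
by a reported (mean, standard error) pair through closed-form
method-of-moments fits (`fit_distribution_from_moments()`). The PSA
samples every parameter independently per draw, rebuilds both arms, and
records $(\Delta E, \Delta C, \mathrm{INMB})$. Three contracts matter:

* **determinism**: one seeded generator, draws consumed in declared
  parameter order; identical seeds give bitwise-identical tables;
* **rejection, not clamping**: a sampled set violating model invariants
  is rejected and redrawn (clamping would silently distort the
  distribution); the run aborts if rejections exceed 5 % of the
  requested draws, naming the distributions involved;
* **no correlation structure**: draws are independent in this version;
  correlated sampling needs covariance inputs early-stage evidence
  rarely has.

`ceac()` summarises the draw cloud as the probability of
cost-effectiveness over a $\lambda$ grid; draws with INMB exactly 0
count as not cost-effective. Deterministic companions: `run_scenarios()`
re-evaluates named override sets on top of the base case (the base case
is always row 1), and `one_way_tornado()` pivots each parameter alone to
its 2.5th/97.5th percentiles (±20 % for fixed values), clamping
percentiles to the parameter's valid domain with a warning.

Structural uncertainty (alternative model structures) is out of scope:
the engine deliberately keeps one structure across analyses.

## Instrument mapping

Where health-related quality of life was measured with another
instrument (SF-36, SF-12, SF-6D, 15D, disease-specific scales),
`map_to_eq5d()` applies a *declared* published mapping — linear or
piecewise-linear coefficients with a residual standard error — to
predict EQ-5D utilities. The residual SE is returned so the conversion
uncertainty can be carried into the PSA as the utility's standard error.
Estimating mapping algorithms from raw data is out of scope; scores
outside an algorithm's declared range are refused by default because
extrapolated mappings are unreliable.

## The parameter database

Parameter sets are strict, versioned JSON documents: unknown keys are
rejected, every domain and referential rule is checked at load time, and
`validate_parameter_set()` returns the full error/warning report rather
than stopping at the first problem — the machine-checkable half of a
human review workflow. Defaults representing a population can be
overridden with local data via `merge_overrides()`; every overridden
leaf is re-tagged `user_provided`, so an analysis always discloses which
inputs are local. Life tables are plain CSV (`age,mortality_prob`),
looked up by `floor(age)` without interpolation — annual cycles make
interpolated mortality spurious precision. A table must end in
probability 1 (closure) or be flagged open-ended; a closed table covers
all later ages.

## What the synthetic fixtures emulate — and what they do not

`synthetic_fixture()` stands in for a curated population database. Each
profile (`generic_elderly`, `falls_prevention`, `chronic_disease`) fixes
a condition archetype: a Gompertz-shaped life table (exponentially
increasing hazard, anchored at a plausible hazard for the profile's
start age), incidence/recovery/excess-mortality values typical of the
archetype, utilities and annual costs per state, and an intervention arm
with a seeded relative risk on incidence (0.55–0.9 across profiles) plus
cost differences. A small seeded jitter on the hazard level and costs
makes seeds distinct while keeping every fixture valid.

The fixtures emulate the *shape* of real inputs, not any real
population: mortality is exactly Gompertz (real life tables have infant
and accident humps the model never sees, but the cohorts start at 60+
where Gompertz is a good description), transitions other than baseline
mortality are age-constant, effects are time-constant, and utilities
carry no age decrement. Passing tests therefore demonstrate the
engine's arithmetic, invariants and reproducibility — not the realism of
any particular clinical estimate, which remains the user's evidence
problem.

## Numerical choices

* Row-stochasticity is exact by construction (residual diagonal);
  validation tolerances are 1e-12 for matrix rows and 1e-9 for trace
  rows (accumulated floating-point error over many cycles).
* Rate↔probability conversion uses the constant-hazard forms
  $p = 1-e^{-r\ell}$, $r = -\log(1-p)/\ell$; $p = 1$ is rejected (no
  finite hazard).
* A residual self-transition in $[-10^{-12}, 0)$ is treated as 0;
  anything below is an error naming the state and cycle.
* Ties: INMB exactly 0 counts as not cost-effective; $\Delta E = 0$
  yields no ICER and dominance is classified by the cost sign;
  $\Delta E = \Delta C = 0$ is reported as equivalence.
* Problem sizes in the shipped checks: property tests use hundreds to a
  thousand random models at horizons 10–50; end-to-end checks run all
  three profiles over five seeds with 1000-draw PSAs; moment-recovery
  checks use $10^6$ direct draws. These sizes make Monte-Carlo
  tolerances (3 standard errors) tight enough to be meaningful.

## Known limitations

* Cohort-level only: no microsimulation, so no individual history
  (e.g. time-in-state-dependent mortality) can be represented.
* Only baseline mortality is age-dependent by default; other transitions
  are constant per arm.
* Independent PSA sampling; no probabilistic correlation between
  parameters.
* One absorbing state; tunnel or semi-Markov constructions must be
  encoded as extra explicit states.
* The parameter database is flat files plus provenance tags; the
  surrounding human review and sharing workflow is not part of the
  engine.
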