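---
title: "Methods: threshold pricing of nutrition supplementation alongside ART"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold pricing of nutrition supplementation alongside ART}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutricea)
library(dplyr)
```

## The decision problem

Malnourished adults starting antiretroviral therapy (ART) for HIV die or are
lost to follow-up (LTFU) at high rates in the first six months of treatment,
and the excess concentrates in the lowest body-mass-index (BMI) strata. A
programme considering adding a six-month macronutrient supplement must decide
what the ration may cost: the combined programme should avert a DALY for no
more than ART alone already does. `nutricea` frames this as a threshold
("parity") price problem rather than a conventional incremental
cost-effectiveness comparison — the output is the maximum quarterly
supplement price S\*, per BMI stratum, as a function of the survival and
retention benefit the supplement is assumed to confer.

## Model structure and assumptions

The cohort model has three states — alive/active in care, deceased, LTFU —
and two 90-day cycles. Transitions are unidirectional: death and LTFU are
absorbing within the model horizon (a dedicated sensitivity analysis relaxes
the LTFU exit; see below). Quarterly transition probabilities are conditional
on being alive/active at the quarter start and come from a stratified cohort
disposition table of counts (entering, alive, dead, LTFU per quarter).

Cost accrual follows the convention that every patient entering a quarter
accrues that quarter's full ART cost, with no half-cycle correction; patients
exiting by death or LTFU within the quarter are costed identically, since the
disposition data do not distinguish exit timing. Patients alive and active
after two cycles receive a fixed lifetime programme cost net of the two
quarters of ART already accrued, plus a fixed DALY benefit. Nothing is
discounted inside the engine: the lifetime cost and DALY inputs arrive
pre-discounted (3% upstream) and first-year costs are conventionally not
discounted. These conventions were adopted as a package design decision
because together they make the model's arithmetic agree with the published
benchmark values to well under a tenth of a percent; a half-cycle-corrected
variant does not.

Base economic parameters (`econ_params()`): $556 per patient-year of ART
(hence $139 per quarter), $6,118 lifetime programme cost per 6-month
survivor, 7.3 DALYs averted per survivor. All three are program-level inputs
taken as constants; their derivations (a 45-site costing study, a comparison
against an untreated reference cohort) are upstream of this package.

## Two probability conventions

`derive_transitions()` supports two rounding modes:

* **counts** — exact division of the disposition counts; the natural choice
  for new data.
* **percentages** (default) — each conditional probability is rounded to one
  decimal place in percent and the triple renormalized if its sum is within
  0.1 points of 100% (larger deviations are rejected). This emulates an
  analysis pipeline whose model consumed a published, rounded table rather
  than raw counts.

Both modes are exposed because the original analysis this package
re-implements evidently used rounded inputs: in percentage mode the package
reproduces the published willingness-to-pay values to ≤0.02% and the
threshold-price table to ≤0.4%, whereas raw counts drift by up to ~2% on some
cells. For the packaged table the two modes agree on every probability to a
tenth of a percentage point, so scientific conclusions do not depend on the
choice; percentage mode is the default for reproduction work, counts for
analysis of new cohorts.

Two published values resist exact reproduction under either mode and are
documented rather than tuned for: the mild stratum's WTP ($845.87 published
vs ≈$845.26 computed, 0.07%), and the same stratum's 20%/20% threshold, which
the source reports inconsistently as $5.28 (table) and $5.18 (abstract) —
the package computes ≈$5.18. Neither is used as a strict reproduction
anchor.

## The threshold solve

With WTP fixed at the stratum's ART-alone cost per DALY averted, the parity
condition for a supplement priced S per quarter is linear in S, so
`max_supplement_cost()` solves it in closed form rather than by search:

\[ S^* = \frac{\mathrm{WTP}\cdot\Delta' - C'}{E'} \]

where primes denote the intervention-adjusted model (death and LTFU
probabilities scaled by \(1-r\), mass reallocated to survival), and the
supplement exposure E′ equals the ART exposure (one ration per entered
quarter; the convention that reproduces the published thresholds). Inverse
consistency — substituting S\* back and recovering the WTP to 1e-9 relative —
is enforced by test. The parity frontier (`parity_frontier()`) inverts the
same function: for each mortality reduction on a grid (default resolution
0.005) the matching LTFU reduction is found by bracketed bisection
(`stats::uniroot`, tolerance 1e-6) on a function monotone in `r_ltfu`; grid
points with no root in [0, 1] are omitted, so a zero-price frontier
degenerates to the single point (0, 0).

Degenerate inputs are handled explicitly: a quarter with nobody entering has
no conditional probability and is rejected; zero expected DALYs makes the
cost-per-DALY ratio undefined and is an error rather than an Inf; a negative
S\* (an intervention that worsens outcomes) is returned with a warning rather
than clamped.

## Sensitivity analyses

**ART programme cost** (`art_cost_sweep()`): annual cost C sweeps $500–$1200.
The quarterly cost is C/4 and the lifetime cost is scaled proportionally,
$6{,}118 \times C/556$ — a package design decision, since the upstream
sources do not state how lifetime cost co-moves with annual cost;
proportional scaling reproduces the published $23.83 anchor at C = $1200 to
0.13%. The WTP is recomputed at each C so both arms are priced consistently.

**Return to care** (`ltfu_return_threshold()`): a fraction f of patients
classified as LTFU at 6 months later return, contributing the same lifetime
cost and DALYs as continuous survivors but no second supplement course. Two
conventions are explicit and configurable in code because the source leaves
them unstated: (1) returnees are credited the ART cost accrued before exit —
one quarter for a Q1 exit, two for a Q2 exit — before the lifetime tail is
added; (2) the ART-alone comparator is re-evaluated under the same return
assumption, so parity compares like with like. Under these rules f = 0
reproduces the primary analysis exactly, and S\* declines monotonically in f,
fastest in the severe stratum (the one with most LTFU).

## Supplement costing

`quarterly_cost()` converts a commodity's energy density into the mass
supplying the ration target (default 1,360 kcal/day for 90 days) and
multiplies by price per kg. The daily target is the programme's literal
1,360 kcal; the derivation — half of a 2,100 kcal recommended minimum intake,
inflated 30% for the elevated resting metabolic rate of advanced HIV — yields
1,365 and is provided separately as `kcal_target()`. The cost is computed
from the mass rounded to two decimals (configurable), matching the precision
at which ration tables quote masses and the convention under which all four
published commodity costs reproduce to the cent. The packaged commodity file
stores CSB at $0.481/kg (price tables print $0.48; the published quarterly
cost implies the extra digit). Delivery and supply-chain costs are out of
scope: thresholds should be compared against the *delivered* cost of a
ration, which is context-specific.

## Synthetic cohorts and what the tests show

`simulate_cohort()` draws each stratum-quarter's outcomes as one multinomial
sample at the cohort-count level — sufficient statistics for everything the
model consumes, far cheaper than event streams — with survivors chaining into
the next quarter. `recovery_experiment()` re-runs the full estimation
pipeline on each replicate and summarises estimator distributions against the
known truth; per-replicate seeds are derived from one master seed, so
experiments are reproducible. At the packaged table's scale (5,096 severe
stratum entrants) recovered quarterly probabilities are unbiased to ±0.005,
the spread of recovered S\* shrinks like \(1/\sqrt{n}\), and the 95%
percentile interval of S\* covers the truth in ≥9 of 10 repeated experiments
of 500 replicates (the problem sizes used throughout the test suite).

The generator emulates the multinomial sampling structure of a disposition
table, not real programme data: no covariates (age, sex, CD4 count), no
secular trends in programme quality, no misclassification between death and
LTFU, and no correlation between strata. Passing recovery tests therefore
demonstrates internal statistical consistency of the estimators, not that the
historical table is itself an unbiased measurement of mortality (a known
fraction of "LTFU" in such programmes are unrecorded deaths — one reason the
return-to-care sensitivity exists).

## Known limitations

* The model horizon is two cycles; quarters 3–4 in the table are validated
  and used for cumulative summaries but not by the economic model.
* The comparator is ART alone by construction; the package does not model a
  no-ART arm, hospitalization or other non-ART health-system costs, or any
  effect of supplementation on ART adherence.
* The DALY input is a single constant per survivor; distributional
  (probabilistic) sensitivity analysis is not implemented — the published
  analysis is one-way, and the package mirrors that scope.
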