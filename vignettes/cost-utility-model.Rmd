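---
title: "A lifetime Markov cohort cost-utility model of exercise after early-stage breast cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lifetime Markov cohort cost-utility model of exercise after early-stage breast cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exercea)
```

## The decision problem

A tailored exercise programme (16 sessions with an exercise physiologist
over 8 months, supporting mixed aerobic/resistance exercise) is offered to
women after surgery for early-stage breast cancer, and compared with usual
care. Trial follow-up over 8 years observed lower breast-cancer mortality,
lower non-breast-cancer mortality, slightly lower recurrence and a
first-year quality-of-life gain in the exercise group. The economic
question is whether those benefits justify the programme's cost once the
downstream consequences — recurrence treatment, end-of-life care,
productivity and carer burdens, and the ordinary costs of surviving
longer — are accounted for over the cohort's remaining lifetime.

`exercea` implements this as a five-state Markov cohort model evaluated
from a societal perspective in 2019/20 Australian dollars, with
quality-adjusted life years (QALYs) and life-years as effect measures.

## States and transitions

The five mutually exclusive states are early-stage disease (the whole
cohort starts here at age 52), locoregional recurrence, distant
(metastatic) recurrence, death from breast cancer, and death from other
causes. Both death states are absorbing and no pathway leads back to the
early-stage state. Transitions happen in yearly cycles via
`build_transition_matrix()`:

* **Early-stage row, cycles 0–7 (the trial window).** The arm-specific
  trial probabilities govern: total recurrence (0.0072 exercise / 0.0076
  usual care) split between local and distant destinations in the ratio of
  the literature values (0.007 : 0.018, i.e. 28% : 72%, since the trial
  reports no split); breast-cancer death (0.0059 / 0.0096); and
  other-cause death as `max(life-table q(age), trial non-breast-cancer
  mortality)`. The maximum — rather than the sum — is used because the
  life table and the trial estimate describe the same event, and adding
  them would double-count deaths.
* **Early-stage row, cycle 8 onward.** No continued intervention effect is
  assumed: recurrence reverts to the literature values (0.018 distant,
  0.007 local per year), direct breast-cancer death from the early state
  switches off (after the observation window, breast-cancer death is
  reached only through the recurrence states), and other-cause death
  follows the life table.
* **Locoregional row.** 0.0997/year to distant disease, 0.069/year to
  breast-cancer death, life-table other-cause death, remainder stays.
* **Distant row.** 0.230/year to breast-cancer death, life-table
  other-cause death, remainder stays.

Rows are completed by assigning the residual probability to staying; if
competing exits exceed one the matrix is rejected (and, inside the Monte
Carlo loop, the draw is re-sampled and counted). The cohort runs until age
100 or until fewer than 0.1% remain alive. The length of the trial window
is a setting (`trial_window_years`, default 8), because how trial-based
and literature probabilities should be layered is genuinely open; the
window-substitution rule used here is the reading most consistent with
"no assumption of ongoing benefit".

## Valuation

Utilities: early-stage 0.818 (plus 0.070/0.020 in the first cycle only —
the trial-observed quality-of-life gain, not extrapolated), locoregional
0.670, distant 0.640, death 0. Members dying of breast cancer within a
cycle carry the terminal-disease weight 0.514 on whatever exposure they
have in that cycle.

Costs per cycle combine occupancy costs for early-stage occupants
(follow-up care by year since diagnosis; productivity loss 10,850/year;
carer cost 2,170/year; out-of-pocket expenses 2,538/year in the first two
cycles only) with one-time transition costs (local recurrence
8,679 + 22,785 productivity + 29,295 carer; distant recurrence
27,677 + 34,719 + 56,419; end-of-life care 25,475 for breast-cancer death
and 12,122 otherwise; 149,909 productivity loss when breast-cancer death
occurs before age 65), plus the one-off programme cost 1,344 in cycle 0 of
the exercise arm. Recurrence treatment is assumed completed within a
single one-year cycle, which is why its costs attach to the transition
rather than to occupancy. Treating the early-stage productivity and carer
figures as *annual* accruals (rather than one-off) is a documented choice
(`early_costs_annual`); it is the reading under which lifetime societal
costs reach a plausible scale for three decades of survivorship.

### Exposure, half-cycle correction and discounting

Rewards accrue on *exposure*: end-of-cycle occupancy in every cycle except
the first and last, where the mean of start- and end-of-cycle occupancy is
used (transitions happen mid-cycle on average; the correction is applied
to the endpoint cycles, with a full trapezoid variant available via
`half_cycle = "trapezoid"`). Cycle `t` is discounted by `1.05^(-t)`.

One consequence of the end-of-cycle convention: the fraction dying within
a cycle carries exposure only in the half-cycle-corrected cycles, so the
terminal-utility substitution is implemented on exactly that exposure
(a flow-based decomposition). This keeps the invariant QALY ≤ life-years
true cycle by cycle — a property the test suite asserts, along with exact
equality when all utilities are set to 1.

Headline results report discounted costs and QALYs. Life-years are
reported **undiscounted**: a 5%-per-year discount caps any lifetime at
21 discounted years, so a mean of ~25 life-years for a cohort entering at
52 is only meaningful on the undiscounted scale, and the per-life-year
ICER is the one consistent with that convention. Discounted life-years are
computed and carried alongside (`ly_disc`, `dly_disc`).

## Parameter uncertainty

Each input carries a mean and low/high bounds, read as a central 95%
interval (±10% of the mean where no interval was available, including the
death-from-local-recurrence row, whose printed bounds are inconsistent
with its mean — an apparent typesetting slip). `fit_sampler()` fits, by
method of moments with `sd = (high − low)/3.92`:

* **beta** for probabilities and utilities (uniform(low, high) fallback
  with a warning if the implied variance is infeasible);
* **gamma** for costs and productivity/carer losses;
* **log-normal** for the annual out-of-pocket cost, whose bounds
  (797–9,079 around a mean of 2,538) are multiplicative — the geometric
  mid-point of the bounds nearly equals the mean — so the fit is done on
  the log scale with `meanlog` chosen to preserve the arithmetic mean
  exactly;
* **fixed** for the starting age, which enters one-way analyses (44–60)
  but not the probabilistic one.

### Correlation between arms

The trial-based inputs come in exercise/usual-care pairs estimated from
the *same* trial. Sampling the two members of a pair independently
produces draws in which usual care beats exercise on survival outright —
and a between-arm life-year difference whose lower uncertainty bound is
deeply negative, which is qualitatively wrong for a within-trial contrast:
the sampling uncertainty of the two arms' estimates is not independent of
the common level of risk. The default therefore draws each pair
*comonotonically* (one shared uniform mapped through each arm's fitted
distribution). Marginal distributions — and hence all sampled means — are
exactly unchanged; only the joint behaviour differs, preserving the
trial's relative effect while the level varies.
`arm_correlation = "independent"` restores fully independent draws.
Distinct quantities remain mutually independent throughout.

## Probabilistic and one-way analyses

`run_psa()` (default 5000 iterations) draws one joint parameter vector per
iteration, runs **both** arms on the same draw, and records per-draw
lifetime totals and increments. Summaries use the convention that the
headline ICER divides mean incremental cost by mean incremental effect;
per-draw ICERs feed only the percentile 95% uncertainty interval, ranked
with "dominant" (cost-saving, more effective) below every numeric ratio
and "dominated" above, so a heavily cost-saving tail reports a "dominant"
interval endpoint. The interval drops `floor(0.025 n)` samples from each
end. Cost-effectiveness acceptability curves report, for each
willingness-to-pay `λ` (default grid 0–100,000 by 1,000), the fraction of
draws with positive net monetary benefit `λ·ΔE − ΔC`.

`run_owsa()` pins one parameter at a bound and either re-samples all other
parameters (`mode = "resample"`, matching a one-way analysis run as
repeated simulation) or holds them at their means
(`mode = "deterministic"`). Entries are returned widest bar first.
Pinning the starting age re-ages the entire cohort.

## Numerical choices and problem sizes

Transition-matrix rows are exact to 1e-12; trace conservation is asserted
to 1e-9. The engine is validated against an independent individual-level
microsimulation (200,000 trajectories in the acceptance suite, agreement
within 3 Monte-Carlo standard errors at cycles 1, 5 and 20). The test
suite sizes its Monte Carlo runs to keep the whole suite around a minute:
5000 draws for the headline probabilistic checks, a few hundred for
behavioural checks, deterministic mode for the broad one-way sweep and 500
re-sampled draws for the headline recurrence pin. Same-seed runs are
byte-identical, including written CSV outputs.

## What the fixtures emulate — and limitations

Two required inputs are tabulated quantities whose source tables are not
available in published form, so the package bundles synthetic stand-ins,
clearly labelled as such:

* **Life table.** A Gompertz hazard `q(age) = A·e^{B·age}` calibrated
  through `q(52) = 0.002` and `q(90) = 0.12`, anchors consistent with
  published Australian female period life tables (`calibrate_gompertz()`
  solves the two-point system exactly). It is smooth where a real table
  has structure, and it is capped at 0.99.
* **Follow-up care costs.** AU$900, 700, 500, 400, 300 for years 1–5
  after diagnosis, then a constant AU$250/year — a Medicare-style taper
  (GP visits, specialist reviews, mammography) from intensive early
  surveillance to maintenance.

Both are overridable by CSV, and policy use should override them. Because
these stand-ins (and other unpublished calculation details, such as the
precise layering of trial and literature probabilities) differ from the
original analysis inputs, the pipeline reproduces the *structure* and the
QALY/life-year scale of the published evaluation more faithfully than its
absolute cost level: the reproduction tests in the acceptance suite hold
arm-level QALYs and the cost-effectiveness probabilities within their
tolerance, while the absolute cost level — and with it the incremental
cost and the ICERs — sits below the published point estimates. The
conclusion the model supports (the programme is cost-effective at
AU$50,000/QALY with high probability) is insensitive to this gap, and the
tornado analysis identifies the same qualitative drivers: the trial-based
recurrence and mortality pairs carry by far the widest bars, and pinning
exercise-arm recurrence at its high bound multiplies the ICER several
fold — though from this parameterisation's lower cost base it does not
cross the AU$50,000 threshold, and no other single-parameter pin
approaches it in deterministic mode.

Other limitations are structural and deliberate: no tunnel states (so
time-in-state does not modulate recurrence risk), no individual-level
heterogeneity in the cohort engine (the microsimulation exists only as a
test oracle), no correlation structure beyond the arm pairs, no
value-of-information analysis, and no re-derivation of the input estimates
from their primary sources.
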