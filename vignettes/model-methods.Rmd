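---
title: "A Markov cohort model for population-based BRCA testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for population-based BRCA testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brcacea)
```

## The decision problem

Clinical-criteria/family-history (FH) based BRCA1/BRCA2 testing misses most
carriers: a woman without a recognised family history is never offered a
test, and her first sign of carrying a mutation is often the cancer the test
could have helped prevent. `brcacea` implements a lifetime decision model
that compares two strategies for women aged 30 and over:

* **Population testing** — every woman is offered pre-test counselling and a
  BRCA1/BRCA2 test (70% accept);
* **Clinical-criteria/FH testing** — only the roughly 1% of women whose
  family history meets current clinical criteria (about 10% a-priori
  mutation probability) are offered testing.

Detected carriers can opt for risk-reducing mastectomy (RRM), risk-reducing
salpingo-oophorectomy (RRSO, with or without hormone replacement therapy,
HRT), and breast-cancer chemoprevention; undetected carriers receive none of
these. The model tracks breast cancer (BC), ovarian cancer (OC), excess
fatal coronary heart disease (CHD) after premenopausal RRSO without HRT, and
background mortality, and accrues discounted costs and quality-adjusted life
years (QALYs) from both payer and societal perspectives for six country
profiles (UK, USA, Netherlands, China, Brazil, India).

## Model structure

The engine is an annual-cycle Markov cohort model over a single shared state
space of 37 states (`build_state_space()`): nine healthy states (non-carrier,
undetected carrier, and seven detected-carrier intervention states — none,
chemoprevention, RRM, RRSO ± HRT, RRM+RRSO ± HRT), four cancer pathways
(BRCA-associated and sporadic BC and OC, each with five post-diagnosis years
and a long-term survivor state), and four absorbing death states (BC, OC,
CHD, other causes). Both comparator arms use the same state space and the
same transition matrices; they differ only in the initial split of carriers
between detected and undetected states and in the cycle-0 testing-pathway
costs. Carrier mass is conserved: detected plus undetected carriers equal
the population prevalence `p1` in both arms.

Within a cycle, competing events (BC incidence, OC incidence, fatal CHD,
background death) are combined by converting annual probabilities to rates,
summing, converting back, and apportioning the total event probability
proportionally to the rates. This is order-independent, which matters
because no event ordering within a year is specified anywhere in the inputs.

Interventions are applied deterministically at the published median ages:
RRM at 37 (uptake `p2`, with chemoprevention uptake `p15` among carriers who
decline RRM) and RRSO at 40 (uptake `p8`, independent of RRM status; a
fraction `p13` take HRT until age 51). The redistribution is a
row-stochastic matrix applied to the state vector at those cycles, so mass
conservation is preserved exactly. Because the state list has no
chemoprevention-plus-RRSO state, carriers on chemoprevention who take RRSO
move to the RRSO-only states — the chemoprevention course is treated as
ended, and the (stronger) RRSO breast-cancer hazard ratio applies from then
on.

Intervention effects multiply the carrier incidence schedules: RRSO reduces
OC risk by `p3` = 0.96; RRM alone reduces BC risk by `p7` = 0.91; RRM with
RRSO by `p10` = 0.95; RRSO alone applies the hazard ratio `p9` = 0.49 to BC
incidence; chemoprevention applies the hazard ratio `p14` = 0.71. Hazard
ratios are applied directly to annual probabilities, a good approximation
while annual risks are small (carrier BC incidence peaks at ~4% per year in
the synthetic schedules).

Cancer survival uses five-year survival fractions: a flat annual
cancer-specific death probability `1 - s^(1/5)` is applied during the five
post-diagnosis years (so that five-cycle survival equals `s` absent
background mortality), after which mortality reverts to the background life
table. Survivors after year five carry the healthy utility; the five
post-diagnosis years traverse the four published stage utilities with a
2/1/1/1-year split (early, advanced, recurrent, end-stage), the same split
used for stage-specific treatment costs. The split is a modelling choice:
stage durations are not published, and only the five-year total is
constrained by the survival data.

Excess CHD after premenopausal RRSO without HRT is modelled per cycle: from
the RRSO age to the end of follow-up these states carry an annual CHD event
probability `p11` = 0.0072 of which the fraction `p12` = 0.0303 is fatal
(transition to CHD death). This is the only reading expressible as a Markov
transition; note that over a 43-year horizon it accumulates roughly a 0.9%
absolute fatal-CHD risk for the exposed group, so the per-cycle reading is
conservative relative to quoted lifetime figures, and the excess-CHD death
counts it produces are small (of order 1-20 per million women), matching the
order of magnitude of published impact tables.

## Timing conventions and discounting

Cycle length is one year and **no half-cycle correction** is applied — state
membership is valued at cycle start, one-off event costs are charged in the
cycle whose transition produces them, and testing-pathway costs fall at
cycle 0 undiscounted. This convention makes accruals exactly geometric: a
permanently healthy cohort discounted at rate `r` over `T` cycles accrues
`sum((1+r)^-(0:(T-1)))` life-years, which the test suite checks to 1e-9.
Discounting runs at 3%/3% in WHO mode, or at country-recommended rates in
local mode (UK 3.5%/3.5%; Netherlands 4% costs / 1.5% effects).

## Economic accounting

Payer costs comprise the testing pathway (pre-test counselling and test for
testers, post-test counselling for detected carriers and for the 2% VUS
fraction of testers), surgical procedures and chemoprevention at the uptake
cycles, annual MRI/mammography screening for unmastectomised detected
carriers (to age 70), HRT to age 51, bone-health monitoring after RRSO, CHD
event treatment, and stage-based cancer treatment.

The societal perspective adds a three-component human-capital productivity
loss, each component scaled by labour-force participation and truncated at
the retirement age: **temporary disability** (workdays absent after
diagnosis at the age-specific daily wage), **permanent disability** (the
discounted wage stream from diagnosis to retirement scaled by an effective
reduction combining workforce departure and reduced hours), and **premature
mortality** (the full discounted wage stream from death to retirement,
applied to cancer and excess-CHD deaths). The identity `societal = payer +
productivity loss` holds exactly and is asserted in tests. Background
(other-cause) deaths carry no productivity loss: they occur at nearly equal
rates in both arms, and attributing them would swamp the disease-attributable
signal the comparison is about.

Event counts (BC/OC cases and deaths, excess CHD deaths) accumulate
undiscounted and are reported per million women; national totals multiply
the per-million difference by the female population over 30 divided by 1e6,
rounded half away from zero (matching the integer convention of published
impact tables).

## Uncertainty analysis

* **Scenarios**: `p9 = 1` (no BC protection from RRSO), `p13 = 0` (no HRT),
  half RRM uptake (0.235), half RRSO uptake (0.275), and a $100 test.
* **One-way**: probabilities and utilities vary over their 95% intervals
  (±10% where none is published), costs ±30%, clipped to support; the
  tornado orders parameters by absolute ICER spread.
* **PSA**: probabilities draw from Beta, utilities from log-normal
  (truncated at 1 by resampling — a utility cannot exceed perfect health),
  costs from Gamma distributions, all fitted by method of moments with
  SD = (high − low)/(2 × 1.96) when an interval is given (intervals are read
  as normal-theory 95% CIs on the stated scale; parameter-specific mappings
  are not published). One master seed, draws taken parameter by parameter in
  the documented catalogue order, so runs are bit-reproducible.
* **CEAC**: at each willingness-to-pay `w`, the proportion of draws with
  non-negative net monetary benefit `w·ΔQALY − ΔCost`. The net-benefit rule
  is used instead of comparing raw ICERs because it classifies cost-saving
  draws (negative ΔCost, positive ΔQALY) correctly.
* **Threshold search**: bisection on the test cost for
  `ICER(cost) = WTP` within $1 per QALY, after probing that the ICER is
  increasing in the test cost. Since the test cost does not enter the
  transition dynamics, the cohort traces are computed once and only the
  accrual is repeated per probe.

The FH arm's initial algebra forces detected + undetected carriers to equal
`p1` (the published FH-negative prevalence `p6` is used as a cross-check,
and an alternative `p6`-based split is available via
`make_fh_arm(split = "p6")`; the two agree to about 3e-5 in absolute carrier
mass).

## What the synthetic data emulate — and what they do not

The model's external inputs (WHO life tables, national cancer-registry
incidence, CONCORD survival, wage schedules, country cost appendices) are
not redistributable, so `make_country_fixture()` generates synthetic
stand-ins with the statistical structure the analysis relies on:

* **Life tables**: Gompertz hazard `h(a) = b·exp(c(a−30))`, with `b`
  calibrated by root finding so life expectancy at 30 matches each country's
  cycle count (e.g. 83 for the UK's 53 cycles, 68 for India's 38), verified
  against an independent curtate-expectation summation to ±0.5 years.
* **Incidence**: unimodal log-normal-shaped curves in age. Carrier
  schedules add an earlier-peaking excess on top of the sporadic curve (so
  carrier ≥ sporadic holds pointwise by construction) and are calibrated by
  root finding so cumulative carrier risk to age 80 is 0.70 for BC (within
  the published 69–72% band) and 0.305 for OC (midpoint of the published
  17–44% band); about 10% of carrier BC risk falls before age 40, matching
  the shape of published penetrance curves. Sporadic cumulative risks use
  country anchors of realistic magnitude (e.g. ~11.5% BC in the UK, ~1.6%
  in India).
* **Costs and wages**: a baseline cost schedule at UK-like magnitudes
  scaled per country by a price factor, with the $200 test price left
  unscaled; humped age-earnings curves peaking near 47, scaled to country
  wage levels; temporary/permanent disability magnitudes (110 workdays
  absent, 15% hours reduction, 10% departure) are explicit placeholders.

Because these are emulators, passing tests demonstrate that the *method* is
implemented correctly — conservation, oracle equivalence against a seeded
200,000-individual microsimulation, calibration, discounting identities,
directional responses, reproducibility — not that the package reproduces
published country ICERs to the dollar. Headline deterministic results
(ICERs in the tens of thousands of $/QALY, societal below payer everywhere,
thousands of BC and hundreds of OC cases prevented per million, India the
least affordable setting with a test-cost threshold around $100) match the
published pattern qualitatively; the national impact-scaling identities,
which depend only on printed per-million inputs, are reproduced exactly.

## Numerical choices

* Transition-matrix rows are validated to sum to 1 within 1e-9 at build
  time; trace rows are checked to 1e-10 in tests.
* Beta moment fits reject SDs at or above `sqrt(m(1−m))` rather than
  silently clamping; zero SDs (or degenerate intervals) produce point
  masses.
* Life-table and incidence calibrations use `uniroot` on log-scale
  parameters with tolerances well below the assertion bands.
* ICER classification thresholds are inclusive (an ICER exactly at 1× GDP
  per capita is "highly cost-effective").
* Rounding: life-days gained to one decimal; national impact counts half
  away from zero to integers.
* Problem sizes used by the test suite — a 200,000-individual
  microsimulation oracle, 1000-draw PSA reproducibility runs, 1e6-draw
  moment checks — were chosen to make sampling error negligible relative to
  the assertion bands while keeping the default suite in the minutes range.

## Known limitations

* One first cancer only: BC and OC are mutually exclusive and absorbing
  into survivorship; second primaries and recurrence beyond the four-stage
  utility path are not modelled.
* Uptake is a one-off redistribution at the median intervention ages, not a
  time-varying process; OC screening is excluded (no mortality benefit).
* The per-cycle CHD operationalisation is conservative relative to quoted
  lifetime absolute-risk figures (see above).
* Cost schedules, wage curves and disability magnitudes are synthetic
  placeholders pending country-specific appendix data; all currency fields
  are unitless numbers documented as 2016 USD PPP, and no currency
  conversion is performed.
* Cascade testing of relatives, prenatal/pre-implantation pathways, VUS
  management beyond counselling cost, and value-of-information analysis are
  out of scope.
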