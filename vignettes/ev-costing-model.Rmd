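---
title: "The workload equivalent-value costing model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The workload equivalent-value costing model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evcost)
library(tibble)
```

## Why workload normalization

Community health centers deliver dozens of heterogeneous services — a
15-minute consultation, a home visit, a year of hypertension management,
running a center-wide health-education program — through the same small
teams, without departmental cost accounting. Classical step-down
("ladder-sharing") costing needs cost centers and reliable indirect-cost
allocation keys, neither of which exists in this setting. The model
implemented here instead converts every service into a common workload
currency and prices that currency.

The benchmark is a **standard clinic visit**: a family physician
consulting one patient for 15 person-minutes, defined to be one
**equivalent value (EV)**. Any service with workload indicator $w$
person-minutes per delivery unit has

$$\mathrm{EV} = \frac{w}{15},$$

so a 60-minute home visit is 4 EV. Workload indicators are set per
*stratum* (urban and suburban in the bundled data) because population
density and the delivery model change the staff time a service needs.
Strata are free-form labels in this package; nothing restricts the model
to two.

With annual service volumes $v_s$ and per-unit EVs $e_s$, the measured
workload of a facility set is $\sum_s v_s e_s$. Services outside the
enumerated taxonomy were judged by provider group interviews to account
for a fixed share $u$ (default 10%) of *total* workload, so

$$\mathrm{EV}_{\mathrm{total}} =
  \mathrm{round}\!\left(\frac{\sum_s v_s e_s}{1-u}\right),$$

a share of the total rather than a markup on the measured sum (the
imputed residual equals measured/9 at $u = 0.1$). The cost of one EV is
then total annual expenditure over total EV, decomposable by input
category (human resources, materials, public funds) because each
category's expenditure shares the same denominator. A program's cost is
its EV total times the cost of one EV; dividing by the population served
gives the per-capita cost, and subtracting the government's per-capita
allocation gives the funding gap.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `benchmark()` workload | 15 | person-minutes | denominator of every EV |
| `uplift_share` | 0.10 | fraction of total EV | from provider interviews; applied once per scope, never per facility |
| `reporting_policy()` mode | `"published"` | — | see below |
| `money_decimals` | 2 | decimals | cents |
| program selector | `"nephsp"` | category or service ids | the ten essential public-health services |

## Reporting policy: why rounding is a first-class object

Published costing tables chain *rounded* intermediates: the pooled cost
per EV is printed as 1.87 USD and the program cost as
5,514,777 × 1.87 = 10,312,633 USD, which only reproduces if the
multiplication uses the rounded 1.87, and the per-capita figure 7.95
only reproduces if the division starts from the whole-dollar 10,312,633.
`reporting_policy("published")` encodes exactly this chain (half-up
rounding to cents, whole dollars, and two-decimal percent shares);
`reporting_policy("full_precision")` keeps full floats everywhere, in
which case category decompositions sum exactly to their totals and a
planted ground truth is recovered to machine precision. The same open
question arises for stratum per-capita costs — the source does not say
whether rounded stratum costs per EV (1.71/2.05) fed the chain — and
both choices reproduce the printed 7.31/8.65; published mode uses the
rounded values for consistency with the pooled chain.

Half-up ("commercial") rounding is used throughout rather than R's
round-half-to-even, implemented with a `sqrt(.Machine$double.eps)` nudge
so that decimal ties such as 1,993,810 × 2.05 = 4,087,310.5 — which sit
a few ulps below .5 in binary — round up as they would on paper.

## The bundled reference data and its quirks

`beijing_fixture()` loads the packaged encoding of a 2010
expenditure-and-volume survey of 17 Beijing community health centers (7
urban, 10 suburban; 1.3 million residents served): a 27-service workload
catalog, stratum-level expenditures and populations, and measured
category EV totals. Three source quirks are handled explicitly rather
than silently:

* The urban infectious-disease row prints an EV (94.24) inconsistent
  with its own workload (5,913.63/15 = 394.24) and with the
  rule-consistent suburban row; the fixture stores the workload and
  derives the EV, treating the printed value as a misprint.
* The printed stratum EV totals (7,443,417 urban; 6,612,985 suburban)
  each differ by 1 from both the uplift rule and the sum of their own
  printed rows (7,443,418; 6,612,984); tests accept ±1. The pooled
  total 14,056,402 is exact.
* The published pooled expenditure rows differ from the sum of their
  stratum columns by under 0.4 USD (display rounding), and the total
  served population is printed as both 1,296,403 and 1,296,408. The
  aggregates use the published pooled rows and the 1,296,408 figure
  (the per-capita result is 7.95 USD either way).

Stratum populations are reconstructed as published per-center averages
times center counts (117,687 × 7; 47,260 × 10), the only form in which
the source states them.

The per-category per-capita cells of the published breakdown are not
reproducible cell-by-cell under any single rounding chain (two of the
nine cells differ by one cent from every chain we tried); the report emits
that decomposition under the documented chain, and only row and column
totals are treated as reproduction targets.

## The synthetic generator and what passing tests mean

`generate_panel()` emulates the reference study design: 17 facilities in
a 7/10 urban/suburban split, 27 services across the five measured
categories, category EV shares near the reference workload profile
(35.7/4.3/10.2/6.3/43.6% of measured EV), expenditures split
66/10/24 across human resources, materials and public funds, and
facility populations drawn between 30,000 and 160,000 residents.
Service-level volumes are unpublished in the source, so realism is
calibrated only at the category level: volumes are drawn log-normally
per facility and service, rescaled within each stratum to the share
profile, and rounded to whole delivery units.

Expenditure is *constructed*, not drawn: each stratum's total is the
planted cost per EV times the stratum's total EV (taken after the
uplift's integer rounding — constructing it before rounding would leave
a ~1/total-EV discrepancy), split across input categories by the share
vector and across facilities in proportion to their measured EV. A
full-precision report must therefore recover the planted values to
machine precision, and the test suite checks this across 100 seeds.

Passing these tests shows the arithmetic pipeline is exact and
internally consistent. It does *not* validate the workload indicators
themselves, the 10% residual share, or any behavioral feature of real
demand (seasonality, referral patterns, volume–price feedback), none of
which the generator models.

## Scenarios

`scenario()` captures the intended dynamic repricing mechanism as a pure
transformation: expenditure and volume multipliers, workload
(protocol-revision) overrides, added services with expected volumes, an
allocation change, and population growth. Two design choices were
genuinely open:

* An added service's expected stratum volume is distributed across that
  stratum's facilities in proportion to population served — population
  is the only size variable guaranteed to exist for every facility.
  Expected volumes are always scenario *inputs*; the model never
  forecasts demand for a new service.
* The uplift share is not a scenario field: it came from provider
  interviews, not from the perturbed quantities, so it stays fixed
  unless changed explicitly at costing time.

Multiplicative scenarios compose (applying two equals applying their
product), the identity scenario is a fixed point of the whole pipeline,
and a zero-volume added service changes no cost output; all three are
tested.

## Problem sizes and degenerate inputs

The test suite runs on the bundled 17-center data, synthetic 17 × 27
panels (100 seeds for ground-truth recovery), and 2–5-facility ×
2–5-service panels that are checked against an independent straight-line
reimplementation of the whole chain. Degenerate inputs are defined, not
accidental: zero expenditure with positive workload prices an EV at
0.00; zero total EV raises a division error naming the scope; an empty
facility set or empty program selector is an error; a negative funding
gap is reported as a surplus.

## A worked chain

```{r worked}
fx <- beijing_fixture()
rep <- cost_report(fx$aggregates, program = "nephsp",
                   allocation_per_capita = fx$allocations[["2011"]])
rep
glance(rep)
```

## Limitations

Costs are protocol-based — staff time a service *should* take — not
observed process costs, so results are planning figures, not
reimbursement claims. The EV currency prices only personnel time and
count; capital, equipment intensity, and quality differences between
services are invisible to it. Income-side accounting and currency
conversion are out of scope.
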