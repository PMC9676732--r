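---
title: "Estimating maternal orphans due to cancer: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating maternal orphans due to cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canorphans)
```

## The problem

A maternal orphan is a child under 18 whose mother has died. When a woman
dies of cancer at age $md$ in a reference year, the number of her children
still under 18 is not observed in mortality statistics, but it can be
estimated demographically: her birth cohort's age-specific fertility rates
over the previous 18 years say how many children she is expected to have
had at each age, and child lifetables say how many of those children are
expected to still be alive. `canorphans` implements this estimator at the
level of country, cancer site, single-year maternal age at death and child
birth year, together with a prevalence estimator that accumulates surviving,
still-minor orphans from deaths in earlier years, and a microsimulation
oracle that validates both.

## New orphans

For country $c$, cancer site $t$ and maternal age at death $md \in [15, 67]$,
expected new orphans in reference year $R$ (2020 by default) are

$$\mathrm{NMC}_{c,t,md} = D_{c,t,md} \sum_{y=R-18}^{R-1}
  \mathrm{RR}_t \, F_c(y, ma) \, S_c(y), \qquad ma = md - (R - y),$$

where $D_{c,t,md}$ are single-age deaths (5-year bands spread uniformly,
divided by five), $F_c(y, ma)$ is the fertility rate per woman in calendar
year $y$ at age $ma$ (a step function on the 5-year age x 5-year period
grid, zero outside ages 15--49), and
$S_c(y) = \exp\{-\sum_{x=0}^{R-1-y} M_c(x, y+x)\}$ is child survival from
birth year $y$ to the reference year, with the hazard at age $x$ read in
calendar year $y + x$. Hazards are treated as annual cumulative-hazard
increments and summed directly; no actuarial $a(x)$ correction is applied.
Because fertility is zero beyond age 49, women dying at 68 or older cannot
leave minor children, hence the upper limit $md = 67$.

$\mathrm{RR}_t$ corrects cohort fertility for cancers whose risk depends on
parity: 1.1 for cervical cancer, 0.8 for ovarian cancer, and 0.93 for breast
cancer deaths over age 50 (the breast association is established at
postmenopausal ages only). All other sites use 1. The table is an editable
YAML configuration (`inst/extdata/scenarios.yaml`).

## Prevalent orphans

Point prevalence at mid-reference-year accumulates deaths over
$yd = R-17, \dots, R-1$:

$$\mathrm{PMC}_{c,t} = \sum_{yd} \sum_{md=15}^{67} D_{yd,c,t,md}
  \sum_{y=R-18}^{yd} \mathrm{RR}_t \, F_c(y, md - (yd - y)) \,
  P_c(\mathrm{U18} \mid y, yd),$$

where $P_c(\mathrm{U18} \mid y, yd)$ is zero for children born in or before
$R - 18$ (they are adults by mid-reference-year) and otherwise equals
survival with baseline hazards up to the maternal death and hazards
multiplied by the bereavement mortality rate ratio (MRR) afterwards:

$$\exp\Big\{-\sum_{x=0}^{yd-y} M_c(x, y+x)
  \;-\; \mathrm{MRR} \sum_{x=yd-y+1}^{R-1-y} M_c(x, y+x)\Big\}.$$

With MRR = 1 this collapses exactly onto the plain survival used for new
orphans; the package asserts that collapse in its tests. Two boundary
conventions differ between the estimators and are deliberately preserved
rather than harmonized: the new-orphan sum stops at births in $R-1$, while
the prevalence inner sum includes births in the death year itself (a
mid-year birth precedes a mid-year death), and the new-orphan window admits
children born in $R-18$ while the prevalence under-18 filter excludes them.
The prevalence output therefore retains both the death year and the birth
year so the consistency identity between the two estimators can be checked
on the unambiguous slice.

**Historic deaths.** Cancer-death tables are typically available for a
single reference year, so deaths in year $yd$ are reconstructed by applying
the reference year's age-specific mortality rates to that year's female
population, scaled by a trend multiplier: S1 stable ($1$), S2 rising 1%/year
toward the reference year ($0.99^{R-yd}$), S3 falling 1%/year
($1.01^{R-yd}$), and S4 mixing S2 for low/medium-HDI with S3 for
high/very-high-HDI countries (HDI category taken at the reference year;
historic HDI is not modelled). Multipliers apply uniformly across sites.
`sensitivity_grid()` sweeps trend x MRR combinations (MRR labels a--e map to
1.25, 1.5, 2.0, 2.6, 1.0).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `ref_year` | 2020 | calendar year | reference year of deaths and ages |
| `rr_table` | cervix 1.1, ovary 0.8, breast >50 0.93 | factor | parity correction |
| `trend` | S1 | – | historic mortality trend |
| `mrr` | a (1.25) | rate ratio | bereaved-child excess mortality |
| `include_ref_year_half` | off | – | add half the reference-year minors to prevalence |

The half-year flag probes the ambiguity between a prevalence window written
"mid-year to mid-year" and a death-year sum that stops the year before the
reference year; it is off by default so the default estimate follows the
formula as written.

## Numerical choices

Fertility lookup is a step function on the published 5-year grid; no
interpolation rule is imposed. Deaths are spread uniformly within 5-year
bands with no graduation, and the open-ended 85+ band is treated as
5 years wide (its width is irrelevant: those deaths yield no orphans).
Band labels are canonicalized to closed integer ranges; age bands absent
from a death table are treated as zero deaths, and overlapping bands are a
validation error. Fertility periods must tile at least 2000--2019; earlier
periods are accepted, which is what allows the estimator to be run for
historic reference years in the consistency tests. Child hazards supplied
in 5-year bands are expanded by constant repetition across single ages.
The analytic estimators contain no randomness.

## The synthetic world and what it does (not) show

`synthetic_config()` defines the package's test conditions: three countries
spanning the development gradient — high fertility (TFR 4.5, peak age 23)
with high child mortality (infant hazard 0.035), an intermediate country,
and a low-fertility (TFR 1.6, peak 31) low-mortality country — and four
cancer sites (breast, cervix, ovary, lung) with log-normal age-at-death
curves peaking between 50 and 67 and stylized rate levels chosen so that a
simulated population of $2 \times 10^5$ women yields several hundred cancer
deaths, enough for the Monte-Carlo comparison to resolve a few-percent
discrepancy. Population sizes, growth rates and HDI values follow the same
gradient. Rates carry small seeded log-normal jitter (fertility shapes are
renormalized so single-age rates still sum exactly to the configured TFR),
so different seeds give different worlds. Magnitudes are stylized: the
generator emulates the structure of real global tables, not any country's
actual values, so passing tests demonstrate correctness of the estimation
machinery, not the realism of any particular estimate.

The microsimulation oracle simulates women individually: cohorts sampled in
proportion to the single-age female population, annual births as Bernoulli
events with probability equal to the fertility rate (valid because rates
are far below 1; the generator caps them at 0.5), child survival as chains
of annual Bernoulli draws, and cancer death as a Bernoulli draw under the
configured rates. Standard errors come from 10 independent replicate blocks
of women. When fertility and cancer death are independent, death indicators
are drawn before the birth histories and children are simulated only for
decedent women — the same joint distribution at a fraction of the cost.

The parity-dependence switch makes a woman's death hazard for a configured
site proportional to $g^K$, where $K$ is her simulated parity; $g$ is
calibrated per site and cohort (by root-finding) so the decedents' expected
parity is the configured relative risk times the cohort mean, and the
factor is normalized so marginal death rates stay at their configured
values. Because the year-specific birth probabilities vary within a cohort,
the induced per-year fertility ratio is only approximately constant — exact
for a flat schedule — which is the same idealization the analytic RR
correction makes. Calibration constants are reported in the microsim result
rather than assumed.

## Problem sizes and validation design

The shipped analyses and tests run the three-country, four-site world with
$2 \times 10^5$ simulated women per country (per death year, for the
prevalence oracle) and compare analytic totals to the oracle across five
seeds at a three-standard-error band. Degenerate configurations (zero
fertility, zero death rates, zero child mortality) are asserted exactly.
The published global summary-table ratios are reproduced from their printed
numerator and denominator counts, which exercises the reporting arithmetic
(ratio-of-sums aggregation, display rounding) independently of the
estimators.

## Known limitations

The estimator inherits the assumptions of the underlying demographic model:
a decedent's fertility history equals her birth cohort's averages (apart
from the RR corrections), cancer deaths within a 5-year band are uniform
over single ages, historic mortality follows the assumed trend scenarios
rather than observed series, and children's survival depends on the
maternal death only through the MRR multiplier. Paternal orphans are out of
scope, as are uncertainty intervals around the death inputs. Country
alignment between data sources is assumed done upstream: tables are joined
on a shared `country_id` and non-overlapping countries are dropped with a
report.
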