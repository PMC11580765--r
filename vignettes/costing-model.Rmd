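---
title: "The bouillon fortification cost model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The bouillon fortification cost model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsffcost)
```

## The model

`lsffcost` is an ingredient- and activity-based cost model for national
bouillon fortification programs, built from a societal perspective: it
counts the marginal out-of-pocket and opportunity costs of fortification
for industry and government, not the cost of producing bouillon itself.
A program runs for a 10-year horizon on an annual time step. The first
two model years are the start-up phase — planning, equipment purchase and
installation, label redesign, training — during which no fortification
occurs. Years 3–10 are the operational phase: production-line
fortification, internal and external quality control, government
monitoring of factories, ports and markets, and the purchase of premix.
No discount rate is applied and all unit values are constant 2021 USD;
the only quantity that varies over time is the population, so costs tied
to premix volume grow with it while activity-based costs follow their
explicit year schedules.

Total program cost is the exact sum of five components — firm and
government start-up, firm and government operational, and premix — and
the engine enforces that identity to the last unit of currency
(`total_program_cost()` builds the per-year cells and the totals from
the same pass).

### Demand

National bouillon availability (g/capita/day) times population times 365
gives the annual vehicle volume in MT. The volume splits into domestic
and imported streams by the `domestic_share`; within each stream, the
fortified portion is `industrial_share x compliance` — the model's
reading of "75% of cubes fortified to 100% of the standard" is a single
compliance fraction applied identically to both streams. Availability
can be derived from subnational strata (population share x reach x
intake among consumers) or set directly via `availability_override`. The
packaged fixtures carry an override equal to the survey's national
consumption total divided by national population at full precision,
because re-deriving it from per-stratum values that are printed rounded
shifts annual volumes by tenths of a percent. A year is 365 days; there
is no leap-year handling and no partial-year proration — a program year
is wholly start-up or wholly operational.

### Premix

The premix calculator is the cost core. For each nutrient line the
fortificant amount per kg of vehicle is
`target_level x (1 + overage_fraction) / activity`; the overage is a
flat fraction of the target (0.30 for the vitamins in the reference
formulation, 0 for the minerals) standing in for degradation between
production and consumption — no kinetics are modelled. Amounts divided
by the addition rate give premix proportions; proportions times
fortificant prices give per-kg cost contributions; an inert excipient
fills the remaining premix mass at its own price; and a per-kg blender
up-charge is added after excipient costing (so the reference
formulation's $15.35 ingredients + $1.00 up-charge = $16.35). The
addition rate is an explicit scenario input: `suggest_addition_rate()`
offers the smallest 250 mg/kg granule above 110% of the fortificant
subtotal, but never silently overrides configuration, because the
reference program uses 16,250 mg/kg where mechanical rounding of
1.1 x 14,740 would give 16,214. Unit conversions (e.g. folate DFE
equivalence) are the caller's concern via the explicit
`conversion_factor` of `level_from_nrv()`.

Landed premix prices are channel-specific:
`base x (1 + duty) + transport`. The domestic-production channel bears
the premix import duty (premix is always imported); the premix embedded
in imported finished product is priced without the national premix duty
but with transport — the interpretation under which the 8-year premix
total and the ~92/8 domestic/imported premix cost split of the reference
program reconcile to well under 0.1%.

### Cost schedules

Every start-up or operational activity is a `cost_line_item()`:
quantity x unit price, scaled by scope (number of factories, ports, or
national), by a per-year schedule multiplier, and by additive percentage
markups. Additivity matters: the factory equipment base of $140,312
under 10% duty + 10% shipping + 8% VAT gives the published $179,599 only
if the three rates add (x1.28) rather than compound (x1.331). Schedules
express everything time-varying: the inspection-intensity rule (full
inspections for the first three operational years, halved thereafter) is
a `1,1,1,0.5,...` schedule on the factory-inspection items; periodic
household monitoring is a single 1 in its year; the priced-but-dormant
nutrition surveillance item has an all-zero schedule.

Two costs are rates, not line items. Firm
management/overhead/administration is `firm_mgmt_rate` (default 0.05)
times the year's **domestic-channel** premix value — imported product's
premix is managed by its foreign producer — which is why firm
operational cost tracks population growth. Government management is
`gov_mgmt_rate` times the monitoring subtotal; line items carry a
`mgmt_base` flag saying whether they are in that base. The packaged
fixtures flag every monitoring category (factory, import, commercial,
household, surveillance) and exclude social marketing and training: this
is the only reading that reproduces all three published management
values ($5,174 in a plain year, $6,674 in the household-monitoring year,
$4,689 under halved inspections).

One deliberate simplification: factory equipment maintenance is a line
item whose unit price the fixture sets to 7% of the pre-markup
laboratory equipment set (0.07 x 12,539 per factory) — the base excludes
the feeders, which is what the published maintenance figure implies.
Because it is frozen as a price, sweeping the equipment purchase price
does not propagate into maintenance; re-deriving the fixture would.

## Calibrated fixture values

Published tables round unit costs to the dollar while printing exact
subtotals. The Nigeria fixture therefore stores calibrated unrounded
unit values that reproduce the printed subtotals, each documented at its
definition: factory inspection $161.9375 (96 x -> $15,546), import
monitoring FTE $12,617.20 (5 FTE -> $63,086), import/commercial test
reagents $7.63 (-> $3,815 and $4,578) against $8.00 for in-factory tests
(-> $48,000 and $3,840) — the sources print both without reconciling
them, so the fixture keeps per-context values — external test $62.28
(-> $5,979), training session $249.125, government training $4,982.625.
Government start-up line items are not published; the fixture stores
category totals (planning + equipment 80%, social marketing 12%,
training 8%) calibrated so the two-year government total is $716,556.

The Senegal and Burkina Faso fixtures are approximate
(`approximate = TRUE`): their full schedules are not published, so they
carry category-level items calibrated to the published phase totals,
population growth of 2.6%/yr and 2.8%/yr (realistic recent national
rates), and an imported-product premix duty of 0.10 — half the domestic
premix duty — reflecting the published note that premix embedded in
imported bouillon bears a different duty regime in these
import-dominated markets. Their aggregate totals are indicative, not
authoritative; tests assert only the per-consumer cost band.

## Summary metrics

`summarize_costs()` reports cost per MT as total program cost divided by
cumulative fortified MT over operational years, and cost per consumer as
the operational-phase average of annual operational + premix spending
divided by the operational-phase average consuming population. The
per-consumer definition deliberately excludes start-up years from both
numerator and denominator: start-up delivers no fortified product to
anyone, and this is the definition under which all three countries'
published per-consumer figures are reproduced. Display rounding (whole
dollars, whole percent shares, cents per consumer) happens only in print
methods; all internal arithmetic is double precision.

Degenerate inputs are handled, not refused: zero compliance zeroes the
premix and the firm management charge while leaving every
government cost unchanged; zero fortified volume flags `cost_per_mt` as
`NA` (`zero_fortified = TRUE`) rather than erroring; an all-zero price
vector yields a zero-cost program.

## The random scenario generator

`random_scenario(seed)` exists for property testing, not realism. It
draws populations of 1–300 million with smooth growth, 1–15 strata with
shares normalised to one, 1–6 nutrients with positive prices, bounded
shares/duties/rates, a handful of random line items, and an addition
rate of `ceiling(1.1 x fortificant subtotal)` so every draw is feasible.
It emulates the *structure* of a country configuration — enough to
exercise validation, the additive identity, homogeneity, monotonicity
and the brute-force oracle across a wide parameter box. It does not
emulate real data's features: correlated reach and intake, realistic
price ratios between fortificants, or coherent year schedules. Passing
property tests therefore demonstrate the arithmetic is right everywhere
in the box, not that any random draw resembles a real program; realism
lives in the packaged fixtures.

## Verification strategy and problem sizes

The engine is checked two ways: against the published reference tables
(the Nigeria fixture end to end), and against an independent
re-implementation — a plain year-by-year, item-by-item loop in the test
helpers sharing no code with the engine — required to agree to 1e-9
relative on random scenarios. Suite sizes: 1,000 seeds for
generator-validity, 200 for the additive identity, 100 for oracle
equivalence; the full suite runs in a few minutes on one CPU and the
full Nigeria run takes well under a second.

## Known limitations

- The model is an accounting identity, not a behavioural one: no demand
  response to retail prices, no price pass-through modelling (premix
  costs are reported by payer category; who ultimately bears them is a
  policy question), no gradual compliance ramp-up.
- Fortificant prices, wages and all unit values are frozen over the
  horizon; `sweep_parameter()` provides one-at-a-time sensitivity, not
  stochastic uncertainty propagation.
- Overage is a flat fraction; no stability kinetics.
- The 8-year government operational total implied by the published
  summary decomposition is ~5% above what the published annual line
  items (with the 50% inspection rule) sum to; the fixture follows the
  line items and does not force-fit the summary figure.
- Senegal and Burkina Faso fixtures are calibrated reconstructions, fit
  for structure and per-consumer magnitude, not for line-item analysis.
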