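---
title: "Methods: the SSNC investment-case model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the SSNC investment-case model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssncinvest)
```

This vignette documents the models behind `ssncinvest`, the assumptions they
make, the conventions chosen where several were defensible, and what the
packaged tests do and do not establish.

## The impact model

Neonatal deaths in the baseline year are `annual_births × baseline_nmr /
1000`. These deaths are partitioned across causes (prematurity, neonatal
infections/sepsis, intrapartum complications, congenital conditions, and a
residual "other") by a `cause_shares` table that must sum to one.

Each intervention is characterised by an effectiveness `e` (the proportion of
cause-specific deaths it prevents at full coverage in the affected group), an
affected fraction `a` (the share of the cause's deaths it can plausibly act
on), and baseline and target coverage. For the interventions acting on one
cause, the proportional mortality reduction in year `t` is the residual
product

$$R_c(t) = 1 - \frac{\prod_i\,(1 - e_i a_i c_i(t))}{\prod_i\,(1 - e_i a_i c_i(t_0))},$$

clipped to `[0, 1)`. Dividing by the baseline-coverage product makes the
projection incremental: pre-existing coverage earns no credit. Applying
interventions sequentially — each to the deaths the previous ones left —
gives exactly the same number, which is why the product form cannot double
count; the test suite verifies the closed form against that sequential brute
force to 1e-12 and checks the combined reduction never exceeds the sum of the
individual ones.

Assumptions worth stating plainly:

- **Constant baseline.** Births and baseline cause-specific deaths are held
  constant over the horizon: no secular mortality trend, no demographic
  projection. Deaths averted are therefore attributable to coverage change
  alone. This is deliberate — the configuration format carries no trend
  inputs — and makes the projection conservative relative to a falling
  baseline only in its denominator, not its difference.
- **Linear coverage ramps.** Only the endpoints of the scale-up are usually
  known; coverage interpolates linearly between them (`build_trajectory()`'s
  `shape` argument is an enum left extensible). Custom per-intervention
  trajectories can be supplied; a trajectory ending before the horizon is
  held flat at its final value thereafter.
- **Affected fraction defaults to 1** where a catalogue gives none; in the
  packaged example only kangaroo mother care carries a partial affected
  fraction (0.47) alongside its 51% effectiveness.
- **Interventions sharing a cause combine multiplicatively** — in the
  packaged example the two sepsis interventions and the two prematurity
  interventions. An alternative reading (effectiveness applied to the
  coverage *change* additively) cannot respect the no-double-counting bound
  and was rejected.

### Calibrated cause shares in the packaged example

The Tanzanian cause-of-death split that the original national analysis fed
its projection is not part of the public record, but its outputs are: the
cumulative lives saved by 2030 and their distribution across causes. The
packaged shares are therefore calibrated: share values proportional to
`target_averted_share_c / S_c` (with `S_c` the summed per-year reduction for
cause `c` over the 2021–2030 ramp), scaled so cumulative lives saved by 2030
equals 80,000, remainder to "other". The published averted-lives split sums
to 104% as printed (48% prematurity, 34% sepsis, 16% pneumonia, 3% + 3%);
pneumonia is folded into the infections/sepsis cause — the intervention
package has no pneumonia-specific item — and the split renormalised. The
derivation ships at `tools/calibrate-cause-shares.R` and is never run at
package load; the fixture stores the resulting literals. With these shares
the projected endline NMR is ~13.3 per 1000, and the share of baseline
deaths averted at the horizon is ~34%. The projection's defining properties
(identity under frozen coverage, monotonicity in coverage, conservation
between deaths and NMR) hold independently of the calibration.

## The costing model

Costing is activity-based and incremental from the provider perspective:
catalogue line items (unit cost × quantity) per hospital level, in constant
2022 US dollars with no inflation adjustment.

- **Setup** (infrastructure, ward furniture & fixtures, neonatal devices) is
  one-off capital, annualised by the capital-recovery factor
  `A(r, n) = (1-(1+r)^{-n})/r` at `discount_rate` 0.03/year — infrastructure
  over 20 years, furniture and devices over 5. The zero-rate limit is `n`.
- **Running** combines human resources (headcounts × 12 monthly salaries from
  a staffing policy table), medical supplies & consumables with a
  `markup_consumables` of 10% over the economic order quantity (applied to
  supplies only, not medicines — the narrower reading of an ambiguous rule),
  neonatal medicines, data & quality-improvement systems, and maintenance
  charged at `maintenance_rate` 3% of the setup total.
- **Scenario A** builds and equips everything new. **Scenario B** is modelled
  as an *expected* per-hospital cost — infrastructure at
  `new_fraction + (1-new_fraction) × renovation_cost_fraction` (0.5 + 0.5×0.2
  = 0.6 of new-build) and other items at the acquisition fraction 0.5 —
  rather than as two half-fleets, so fractional hospital counts never arise.
  Scenario B staffing is its own policy table, not a scaled copy of A's.
- **Staffing counts are policy inputs, not derived.** A helper
  (`staff_from_ratio()`) computes headcounts from cots, staff ratios, shifts
  and a leave uplift, but the packaged example uses the government staffing
  table directly: the published headcounts are not reproducible from the
  stated ratios and shift arithmetic, so the table is authoritative.
- Salaries are not part of the public record (only a reference to the
  national pay scale); the packaged monthly salaries are plausible 2021
  public-sector values chosen once so that human resources land near 60% of
  running costs, and the supplies/medicines/data line items are set so the
  per-hospital running totals match the published figures.

National roll-up multiplies per-hospital costs by hospital counts; totals are
additive by construction and the suite checks scenario B never exceeds
scenario A on any metric across 1000 random configurations.

## Return on investment

Conventions, each configurable, defaults chosen to reproduce the worked
example's arithmetic:

- **Setup to horizon** is `annualised setup × years` — the worksheet
  convention of charging the equivalent annual cost each year of the window,
  undiscounted (the annualisation already embodies the discount rate).
- **Running costs** follow the implementation schedule (fraction of full
  annual running cost per year, non-decreasing, reaching 1.0). The stream
  total is discounted by `cost_discounting = "simple"` — a single flat
  multiplication by `1 − rate` — because that is demonstrably the convention
  of the worked example's totals; `"annual"` (end-of-year NPV from the base
  year) and `"none"` are available, and `npv()` exposes proper per-year
  discounting directly. A sensitivity option (`running_basis = "coverage"`)
  scales running costs by the mean intervention coverage ramp instead of the
  schedule.
- **Benefits** are a lump sum: lives × life expectancy life-years, valued at
  `gdp_multiplier × gdp_per_capita` (default 2.3) or a statistical
  life-year value, discounted once over one life expectancy. Productivity
  gains (lives × 46 productive years × value) discount over
  `labour_entry_age + productive_years` = 66 years by default. The
  life-expectancy lump reproduces the worked example's social-benefit
  present value almost exactly; no integer-year convention reproduces its
  productivity present value (the implied exponent is ≈67.9 years), so that
  figure is matched only approximately (~6%) and both horizons are exposed
  as options.
- **GDP growth** (3%/year) can inflate the life-year value over the window
  (`use_gdp_growth = TRUE`); the default is constant-value, the conservative
  base case.
- ROI is `(social PV + productivity PV) / total costs`; the decomposition
  `ROI × costs = benefits` is exact by construction. Cost per death averted
  is total costs to horizon over cumulative lives saved.

Degenerate inputs are handled explicitly: zero lives saved yields an `NA`
cost per death averted rather than infinity; zero total cost yields `NA` ROI;
`compute_roi()` refuses a zero cost denominator; reductions are clipped below
1 so residual mortality stays positive, and an `effectiveness × affected
fraction × coverage ≥ 1` input is a validation error.

## The synthetic-data generator

`generate_bundle(seed)` draws a full country configuration — demography,
cause shares on the simplex, one or two interventions for each
intervention-bearing cause, a two-level hospital roll-out, cost catalogue,
A/B staffing tables with B at most half of A, a non-decreasing implementation
schedule ending at 1.0, and monetisation constants — from documented ranges
spanning plausible low- and middle-income configurations (birth cohorts
2×10⁵–5×10⁶, NMR 5–40, GDP per capita US$400–8000, infrastructure
US$0.1M–3M). Generation is reproducible from the seed and restores the
caller's RNG state. Degenerate ranges pin fields, which is how the generator
can be collapsed onto a known configuration.

What the generator emulates is the *structure* of real configuration bundles
(internal consistency, ordering constraints, positivity), not their joint
realism: costs are drawn independently rather than correlated with income,
there is no geographic heterogeneity (the rural/urban staffing gap is real
but unmodelled), and cause shares are uniform on the simplex rather than
epidemiologically patterned. Passing the property sweeps therefore
establishes that the engines respect their invariants everywhere in the
configuration space — not that any particular synthetic country is
realistic.

## Problem sizes and test design

The suite runs ~5,000 assertions in under a minute: 1000 synthetic bundles
for the coverage-monotonicity and scenario-ordering sweeps, 200 random cases
for the sequential-oracle comparison at 1e-12, 100 annuity round-trips at
1e-9, and exact or published-precision checks on the packaged example's
setup, running, monetisation and budget tables. The acceptance script
recomputes the per-district-hospital annualised total from the packaged
catalogue at runtime.

## Known limitations

- Mortality only: no morbidity or disability averted, so benefits are
  understated; no stillbirth or maternal effects.
- No demographic projection or secular trend; lives saved are measured
  against a frozen baseline.
- Level-3 intensive-care device costs are only partially representable in a
  level-2 catalogue; patient-perspective and governance bottleneck costs are
  out of scope.
- The published figures for regional referral hospitals are not internally
  consistent under the method that reproduces the district-hospital figures;
  the package reports regional totals as computed rather than forcing them.
- Scenario B's published per-hospital running total cannot be hit exactly by
  the stated blend rules (the computed value is ~5% higher); the blend rules
  are kept and the discrepancy documented rather than tuned away.
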