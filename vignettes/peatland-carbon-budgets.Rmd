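---
title: "Methods: flux harmonization, CO2-equivalent balances, and long-term peatland carbon budgets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flux harmonization, CO2-equivalent balances, and long-term peatland carbon budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peatghg)
library(dplyr)
```

# Scope

`peatghg` does three connected things: it harmonizes a compilation of
greenhouse-gas flux measurements from rewetted peatlands onto a single
canonical scale; it aggregates those fluxes into category-level balances
in CO2 equivalents; and it simulates ecosystem carbon stocks of pristine,
drained and restored ombrotrophic peatlands over a 300-year horizon.
This vignette documents the conventions, parameter defaults and numerical
choices behind each stage, and what the packaged synthetic-data
generators do and do not emulate.

# The flux compilation and its encoding

The packaged table (`read_flux_table()`) holds one row per site and
treatment, spanning five restoration categories: general rewetted
peatlands, rewetted peatland forests, paludiculture (reed/grass,
*Vaccinium* and *Sphagnum* systems), shallow lakes on flooded extraction
areas, and open bogs/fens. Fluxes follow the micrometeorological sign
convention: negative = uptake by the ecosystem, positive = emission.

Three encoding decisions matter downstream:

* **Values are stored exactly as tabulated**, as text: plain numbers,
  ranges (`"-3970 to -5970"`) and spreads (`"-1,609 ± 739"`), with the
  per-study measurement-unit string attached per gas. No conversion
  happens at encoding time, so the provenance of every number is
  preserved and any averaging convention can be reproduced.
* **Rows reporting only some gases leave the others absent**, never
  zero; category statistics are computed over present values only.
* **Typographically ambiguous source cells are flagged, not silently
  resolved.** Published compilations of this kind contain cells whose
  digit grouping or spread notation admits several readings. Such rows
  carry `ambiguous_cell` (and irreconcilable unit footnotes carry
  `ambiguous_unit`) in the `flags` column, with the chosen reading
  explained in the `note` column. One reading is always encoded — a
  pipeline cannot average a shrug — but the flag travels with the value.

Row collapse is deliberately simple: a range contributes its arithmetic
midpoint, a `± spread` entry its central value. The midpoint choice is
linear (shifting both ends shifts the midpoint equally), which is what
makes category means independent of the unit representation.

# Unit harmonization

Every unit dialect in the compilation decomposes into four independent
factors: an amount basis (mass of the element, mass of the gas molecule,
CO2-equivalent mass, or moles of gas), a mass/molar prefix, an area and
a time. `parse_flux_unit()` recognizes the full dialect set and
`convert_flux()` multiplies the value by the product of the factors,
targeting **kg element ha⁻¹ yr⁻¹** (carbon for CO2 and CH4, nitrogen for
N2O). Constants: molar masses CO2 = 44, CH4 = 16, N2O = 44 g mol⁻¹;
element content 12 g C per mol CO2 or CH4 and 28 g N per mol N2O; 1 ha =
10⁴ m²; one year = 365 days = 8760 h (no leap handling — the inputs are
annualized literature values and the effect is below 0.1 %).

Three special cases:

* **CO2-equivalent inputs** (`"t CO2-eq ha-1 yr-1"`) cannot be undone
  into element masses without knowing the upstream weighting, so they
  are rescaled in mass/area/time only and flagged
  `was_co2_equivalent`; element-mass aggregation excludes them.
* **Growing-season rates** (`"g CO2 m-2 d-1"` over a stated season) are
  converted literally per unit time, *not* annualized — no defensible
  season-to-year rule exists without site phenology — and flagged
  `season_only`, which drops them from annual category statistics
  unless explicitly kept.
* **Molar units with an element suffix** (`"nmol N2O-N m-2 s-1"`) are
  read as moles of the gas molecule; the alternative reading (moles of
  N atoms) would halve the value. This is the common reporting
  convention of chamber studies.

## The two unit readings

The source compilation is not internally consistent: its caption states
that tabulated values are in kg C (kg N) ha⁻¹ yr⁻¹, while its per-study
footnotes list original measurement units that for several studies are
irreconcilable with the tabulated magnitudes (the worst case differs by
two orders of magnitude, and is flagged `ambiguous_unit`).
`harmonize_fluxes()` therefore supports both readings.
`mode = "tabulated"` (default) takes the caption at its word; it is the
reading under which the compilation's own published category averages
are recovered, and is used for the headline numbers.
`mode = "footnote"` applies each study's footnote unit literally, which
is the right mode for tables whose unit metadata is trustworthy — the
synthetic generator's output, for instance.

# CO2-equivalent balances

Category statistics are unweighted arithmetic means over collapsed,
harmonized, non-flagged values — one value per table row, no weighting
by study duration or area, matching how such compilations are usually
averaged. Means per gas are then combined:

$$\mathrm{CO_2eq} = \mathrm{NEE}\cdot\tfrac{44}{12}
 + f_{\mathrm{CH_4}}\cdot \mathrm{CH_4}\cdot\tfrac{16}{12}
 + f_{\mathrm{N_2O}}\cdot \mathrm{N_2O}\cdot\tfrac{44}{28}$$

with default factors $(f_{\mathrm{CH_4}}, f_{\mathrm{N_2O}})$ = (25,
298) on the 100-year horizon and (7.6, 153) on the 500-year horizon,
both overridable (e.g. the climate–carbon-feedback variant
$f_{\mathrm{CH_4}} = 34$). Because the combination is linear, the
balance computed from category means equals the mean of per-record
balances whenever every record reports all three gases; with partial
records the two differ, and the package computes from means, warning
when a gas is absent and enters as zero.

Display rounding is half-away-from-zero to whole kg
(`display_round()`), so a mean of −927.5 displays as −928.

A caveat the package inherits from its source: only the rewetted-forest
review-row means are exactly attributable to an identifiable row subset.
The compilation's other published category means (for open peatlands,
paludiculture and the CH4 ladder) could not be uniquely traced to row
subsets, so `balance_report()` computes the package's own analogues from
the full categories rather than claiming to reproduce those figures.

# The long-term carbon model

## State and update order

The simulator (`simulate_carbon()`) tracks five pools in t C ha⁻¹ —
peat, stem, branch, coarse root, harvest residue — plus cumulative
exported timber, at an annual step. Each year, in this fixed order:

1. stem volume grows by the increment schedule and the three stand
   pools are re-derived from volume;
2. the peat pool receives the peat-flux schedule (negative =
   mineralization loss);
3. harvest residues decay first-order, the decayed mass leaving the
   ecosystem;
4. if a clearcut falls on this year boundary, stem carbon moves to the
   export ledger, branches and coarse roots become residues, and the
   stand restarts at age 0.

Both schedules are piecewise-linear in time with constant extrapolation
beyond the last breakpoint; the increment schedule runs on *stand age*
(it restarts after a clearcut), the peat-flux schedule on calendar year.
Schedules are evaluated at the end-of-step year, which pins annual
changes to breakpoint values: in the restored-bog scenario the year-20
annual change is exactly the year-20 breakpoint rate (zero). Harvests
fall at whole multiples of the cycle strictly inside the horizon; a
harvest due exactly at the horizon is not applied, so the final state
describes the mature stand — the convention under which the
whole-horizon mean of a managed scenario reflects a full growth cycle
rather than an arbitrary post-harvest dip.

The run is deterministic; the bookkeeping identity
$\Delta(\text{total} + \text{export}) = \text{peat flux} +
\text{stand growth} - \text{residue decay}$ holds each step to
10⁻⁹ t C (enforced by tests), and a peat pool driven below zero halts
the run with an explicit exhaustion error naming the year.

## Allometry

Stem carbon is `volume × wood density × carbon fraction / 1000`;
branches are 12 % of stem biomass and coarse roots 19 % of above-ground
(stem + branch) biomass, constant across age classes. Wood density
defaults to 420 kg m⁻³ and carbon fraction to 0.5 — typical values for
hemiboreal Scots pine, the dominant species on ombrotrophic peat.
Fine roots are not a pool: their fast turnover is part of net ecosystem
exchange and is absorbed into the peat-flux schedule.

## Scenario defaults

All six scenarios start from 686 t C ha⁻¹ of peat, the stock of a 2 m
deposit at 34.3 kg C m⁻³ (`peat_depth_to_c_stock()`). Increment
schedules (m³ ha⁻¹ yr⁻¹) and initial stand volumes follow the standard
description of these systems: 0 (open bog, from a token 3 m³ stand),
0.1 (continuous-cover bog forest from 100 m³), 4 (drained managed
forest), 6 (managed forest on cut-over fen peat, more fertile after
removal of the *Sphagnum* horizon), and for natural regeneration a ramp
0 → (year 20) → 4 by year 50 → 0.1 by year 160. Managed scenarios
clear-cut every 100 years, stems only.

Peat-flux schedules are the genuinely model-defining choices:

* pristine open bog: +0.22 t C ha⁻¹ yr⁻¹, the long-term bog
  accumulation rate;
* pristine bog forest: +0.072, chosen so that peat accumulation plus
  the 0.1 m³ yr⁻¹ stand increment give an ecosystem gain of about
  0.1 t C ha⁻¹ yr⁻¹;
* drained managed forest: −0.9, the reported long-term mineralization
  loss under continued drainage (1.8 and 1.0 are also reported for
  drained former bogs under other site conditions; both are exposed via
  `peat_loss_presets()`);
* managed forest on cut-over peat: −1.0;
* restored bog: a linear ramp from −2.0 at year 0 (bare, oxidizing
  cut-over surface) to 0 at year 20, then +0.22 — the ramp's endpoint
  places carbon neutrality at year 20, and the post-transition rate
  makes the 20–300-year mean exactly 0.22;
* regenerated unmanaged forest: −2.0 → 0 over years 0–50 (slower
  recovery without active restoration), rising to +0.072 by year 160,
  after which the system behaves like pristine bog forest.

Harvest residues decay at 0.05 yr⁻¹ (first-order), and exported timber
is counted as an immediate ecosystem loss — a conservative convention
that ignores wood-product storage. The residue rate is a plausible
boreal coarse-debris value; the source description is silent on
residues, saying only that stems are removed.

```{r diagnostics}
traj <- simulate_carbon("restored_bog")
glance(traj)
mean_annual_change(traj, 20, 300)
```

# Synthetic data

Two generators make every stage testable without external data.
`generate_flux_table()` draws per-category, per-gas fluxes from a
normal distribution on the canonical scale (a log-normal-magnitude
option exists for heavy-tail robustness checks) and re-expresses each
value in a randomly chosen unit dialect via the exact inverse of the
conversion — so footnote-mode harmonization must recover the generating
means regardless of the dialect mixture. Default truth magnitudes sit
at the compilation's category-average scale, with spreads of 300 (CO2),
80 (CH4) and 0.8 (N2O) kg element ha⁻¹ yr⁻¹ — comparable to the
between-site spread within categories — and a 0.4/0.3/0.2/0.1 mixture
over canonical, chamber-per-hour, per-m²-per-year and tonne/molar unit
families. Values are serialized at 12 significant digits, the practical
exactness limit of the text round trip.

What the generator does *not* emulate: spatial or temporal
autocorrelation, category-specific skew, censoring, or the correlation
between gases at a site. Passing recovery tests therefore demonstrates
the correctness of the harmonization/aggregation pipeline, not that the
pipeline is robust to every pathology of real flux compilations.

`perturb_scenario()` multiplies a scenario's rates and ratios by
independent uniform factors in $[1-a, 1+a]$ while leaving structure
(breakpoint years, harvest cycle, initial stocks) untouched. Zero rates
stay zero, so the restored bog's neutrality year is pinned at the
year-20 breakpoint under perturbation — a property the tests exercise
across 100 seeds.

# Numerical choices and problem sizes

* Equality tolerances: unit round-trips and the bookkeeping identity to
  10⁻⁹ (relative and t C respectively); synthetic recovery judged at
  3 standard errors.
* Ranges are normalized sign-aware (`value ≤ high`) whatever the
  printed order; thousands separators and typographic minus/micro signs
  are normalized at parse time.
* Degenerate inputs: empty tables read as empty (never as zeros), an
  empty aggregation selection returns an explicit zero-row result, and
  `co2_equivalent()` treats absent gases as zero with a warning.
* Test and acceptance runs use the defaults throughout: 300-year
  horizons, 50 records per category × 100 seeds for recovery, 1000
  query points for the schedule-interpolation oracle — sizes at which
  every check completes in seconds on one core.

# Limitations

The carbon model is a bookkeeping scheme, not a process model: peat
fluxes are prescribed schedules, with no temperature or water-table
response, no CH4/N2O dynamics, and no uncertainty propagation. Lateral
dissolved-carbon losses — potentially a large share of a rewetted
site's budget — are not modelled. The flux compilation's caption/footnote
inconsistencies mean the default "tabulated" reading should be treated
as the compilation's own convention rather than ground truth; the
flagged rows mark exactly where that convention is load-bearing.
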