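---
title: "Methods: integrated campus footprint accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated campus footprint accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(campusfp)
```

# The accounting model

`campusfp` treats a campus as a single-year **activity ledger**: rows of
(category, item, quantity, unit), e.g. kWh of purchased electricity, tons
of coal, kg of beef, commuter miles. Ten controlled categories cover the
usual institutional system boundary: purchased electricity, on-campus
stationary fuels, direct (fleet) transportation, commuting, food,
fertilizer, animals, refrigerants and chemicals, wastewater, and direct
water use. Item names are an open vocabulary, because food taxonomies
differ widely between institutions.

Each footprint is a linear functional of the ledger: every record is
multiplied by the matching factors of a per-footprint **emission-factor
table** keyed by (category, item, pollutant form), and contributions are
summed after normalisation:

* **GHG** — CO₂, CH₄ and N₂O mass per activity unit; CH₄ and N₂O are
  converted to CO₂-equivalents with 100-year global warming potentials.
  GWPs are *configuration carried on the factor table*, not package
  constants, because factor vintages differ; the shipped defaults are the
  AR5 100-yr values (CH₄ 28, N₂O 265). Refrigerants are ledgered directly
  in CO₂e (form `refrigerant_CO2e`), since institutions receive them that
  way from refrigerant inventories. Reported in metric tons CO₂e.
* **N** — reactive nitrogen (NOₓ-N, N₂O-N, other N) per activity unit,
  reported in metric tons N. "Virtual" N embedded in food production is
  carried by the food factors.
* **P** — kg P per activity unit, drawn only from food, fertilizer and
  wastewater. P from fuel combustion is negligible at campus scale and is
  excluded *structurally* (the engine filters those categories), not just
  by omitting factors.
* **W** — blue (ground/surface) water, green (precipitation) water and
  direct water use, in m³, with gallons available for rendering.
  Grey water (dilution demand) is not modelled.

Internal units are metric (kg, m³, MJ, km); imperial ledger units (lb,
gallon, MMBtu, mile) are converted on entry through a fixed unit
registry. Conversion is a ratio of anchor factors, hence exact,
associative and invertible to ~1e-16 relative.

**Missing factors contribute zero, with a warning.** The per-footprint
sector tables deliberately omit sectors (P has no energy factors; GHG has
no wastewater-P pathway), so an absent (category, item, form) key is
normal, not an error. The warning (suppressible via
`warn_missing = FALSE` or `options(campusfp.warn_missing = FALSE)`) lists
each unmatched pair once so typos are still caught.

# Projection

Business-as-usual (BAU) ledgers are produced by multiplying each record
by the growth driver mapped to its category. Three named drivers —
projected **population**, **gross square footage** (gsf) and **food
demand** multipliers — plus an identity driver cover the ten categories.
The default mapping (food→food; electricity, stationary fuels,
refrigerants, direct water→gsf; commuting, fleet, wastewater→population;
fertilizer, animals→identity) is a modelling choice the data cannot make
for you: energy scales with built space, people-driven flows with
population. It is explicit configuration (`growth_drivers(driver_map=)`,
drivers YAML) precisely so institutions can re-map categories.

Because the engine is linear, projection is exact: identity drivers
change nothing (bit-for-bit), a uniform driver *g* scales every footprint
by *g*, and composing projections multiplies drivers elementwise. These
identities are enforced in the test suite.

# Scenario composition

A strategy is a declarative transformation with a small vocabulary of
kinds:

| kind | acts on | semantics |
|---|---|---|
| `fuel_switch` | ledger | move `fraction` of the source fuel to the target fuel at equal energy content |
| `efficiency`, `behavior_reduction`, `fleet_improvement` | ledger | multiply targeted quantities by (1 − fraction) |
| `renewable_offset` | ledger | subtract an absolute amount of purchased electricity, floored at 0 |
| `food_substitution` | ledger | move `fraction` of the source food mass to destination foods; total food mass conserved |
| `food_waste_reduction` | ledger | remove `fraction` of the avoidable-waste share of all food |
| `grid_factor_change`, `sourcing_factor_change` | factors | multiply targeted emission factors by (1 − fraction) |

Two of these semantics deserve justification:

* **Fuel switches are energy-based.** "Fuel optimization" must preserve
  delivered heat, so quantities are converted through configurable
  higher-heating-value energy densities (MJ per reference unit,
  `fuel_energy_defaults()`) rather than by mass or volume. Switching 1 t
  of coal (26 GJ) to natural gas therefore adds ≈24.6 MMBtu of gas.
* **Food substitutions conserve mass.** Replacing 20 % of beef with
  chicken moves mass, not meals: the number of meals served stays
  constant while the content changes. Conservation holds to 1e-9
  relative across arbitrary unit mixes (lb/kg) and is a tested invariant.

**Composition is sequential in catalog id order**, each fraction applied
to the *running* ledger. Strategies overlapping on an item (e.g. two
beef-reduction strategies) therefore do not double-count: the second
removes a fraction of what the first left. Strategies on disjoint
(category, item) sets commute exactly. An alternative — interpreting all
fractions against the untouched BAU ledger — was rejected because
composed fractions near 1 could drive quantities negative; the
sequential-running rule cannot, and the applied order is stamped into the
result for reproducibility. Quantities are additionally floored at zero
(with a warning) for absolute-amount strategies such as renewable
offsets.

The default catalog carries 29 strategies: 16 energy/infrastructure
strategies present in both a GHG action plan and an N action plan, and 13
food strategies present only in the N plan. Strategy *structure* (kinds,
plan membership, the named substitutions such as "20 % beef replaced with
chicken") is fixed; numeric parameters that an institution's plan does
not itself state (efficiency percentages, solar MWh, waste shares) ship
as clearly labelled illustrative defaults and are expected to be
overridden via the catalog YAML.

# Damage costs

GHG damage is footprint × social cost of carbon. The SCC default is $30
per t CO₂e — an intermediate value within the $14–$74 global-scale range
of interagency estimates (national-scale estimates run $1–$7) — and is a
plain argument everywhere it is used.

N damage costing needs a *release profile*, not just a total: dollars per
kg differ by chemical form, medium and impacted sector. The profile is
built from the N footprint per category:

* combustion and transport N → air, in its ledgered forms (residual
  "other N" from combustion is treated as NOₓ, its dominant constituent);
* virtual N from food and fertilizer → apportioned into dissolved N,
  NH₃, NOₓ and N₂O by a configurable `apportionment_scheme()` (defaults
  0.50/0.30/0.10/0.10 — roughly half of farm-gate N losses take the
  hydrologic pathway and volatilised NH₃ dominates the airborne rest);
* the dissolved share → split across surface water, groundwater and
  coastal systems by a configurable `hydro_split` (defaults
  0.60/0.25/0.15). How hydrologic N divides among receiving waters is
  site hydrology; the split is configuration, not a package prediction;
* wastewater N → surface water as dissolved N.

Apportionment conserves mass exactly, and the release profile's total
always equals the N footprint.

Unit damage costs (2016 USD per kg N) ship as an explicitly
**illustrative default table** on the scale of regional damage-cost
syntheses (Birch et al. 2011 for the Chesapeake Bay watershed; Sobota et
al. 2015; Compton et al. 2011): airborne NOₓ/NH₃ dominated by human
respiratory health, N₂O by climate, hydrologic N by eutrophication, and
small negative climate entries for aerosol cooling. Negative unit costs
are *only* admitted in the climate sector — the validator rejects them
elsewhere. Dollar values from other currency years are pegged with a
bundled US CPI-U annual series (2000–2020); the adjustment is a pure
index ratio and therefore path-independent.

NOₓ health savings follow the emission-difference formula
`(NOx_BAU − NOx_scenario) × $/ton`, evaluated separately for the ozone
and PM₂.₅ formation pathways; default per-ton costs are again
illustrative placeholders.

# The synthetic campus

`generate_campus_ledger(seed, scale)` emits a complete bundle — ledger,
four factor tables, damage table, growth drivers — for a fictional
mid-size university, so every pipeline stage is testable with no
institutional data. What it emulates:

* all ten categories populated; food items span beef, chicken, pork,
  fish, dairy, eggs, grains, vegetables, fruits, legumes;
* magnitudes of order 10⁵ t CO₂e (GHG) and order 10² t N, so
  percent-change arithmetic runs at realistic dynamic range;
* structural orderings that drive the science: per-kg GHG/N/P/W factors
  beef > chicken > plant staples; natural gas cleaner than coal per MJ
  for both CO₂ and NOₓ (so fuel switching reduces GHG *and* N); food
  ≥ 50 % of the N footprint, as typically reported for institutions;
* growth drivers 1.12 (population), 1.20 (gsf), 1.18 (food) — plausible
  2016→2025 growth for an expanding university.

Only activity quantities are randomised (±10 % uniform jitter under the
seed); factors are fixed. The generator id (`campus-gen-1`) is recorded
in bundle metadata so fixtures stay stable across releases.

What it does **not** emulate: any real institution's numbers. Passing
tests demonstrate the accounting identities (linearity, conservation,
composition algebra, oracle equivalence), *not* agreement with any
published campus inventory — reproducing one requires that institution's
own activity data, factor vintages and strategy parameters, loaded via
`load_supplementary_tables()`. Real ledgers also have features the
generator omits: multi-row categories with mixed vintages, seasonal
structure, and item taxonomies far finer than ten foods.

# Numerical choices and degenerate inputs

* Totals close over both breakdowns (category and form) to 1e-9
  relative; engine-vs-oracle agreement is asserted at 1e-12 relative.
* Empty ledgers are first-class: all totals exactly 0, breakdowns zero
  over the full vocabulary; `percent_change` refuses a zero baseline
  rather than returning Inf.
* Factor lookups are exact string matches on (category, item, form) —
  no fuzzy matching, by design: silent near-matches are worse than a
  loud zero-contribution warning.
* CSV output is deterministic (fixed column order, no quoting, `\n`
  line endings); reports contain no timestamps, so regeneration from
  identical inputs is byte-identical.
* Currency is kept at full precision internally; rendering rounds, the
  arithmetic never does.

# Problem sizes in the test suite

The property suites run on ledgers of up to 200 records: 100 random
ledgers for oracle equivalence, ~1,050 randomized cases for
linearity/additivity/monotonicity, 60 randomized food substitutions, and
full 29-strategy compositions on the seed-42 campus. These sizes exercise
every code path (multi-factor records, unit mixes, empty categories)
while keeping the default suite fast; the engine itself is vectorised and
handles ledgers orders of magnitude larger.

# Known limitations

* Point estimates only — no uncertainty propagation on factors.
* Damage response is assumed linear in release; no thresholds or
  nonlinear dose–response.
* No damage costs for P and W (none exist yet in the literature); the
  table format will accept them when they do.
* Implementation costs of strategies are out of scope; damage-cost
  savings are avoided damages, not net benefits.
* Single-year snapshots; a time series is a list of ledgers, and no
  demographic forecasting is attempted — growth multipliers are inputs.
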