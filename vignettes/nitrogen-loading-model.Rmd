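---
title: "A dynamic parcel-level nitrogen loading model with groundwater lags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dynamic parcel-level nitrogen loading model with groundwater lags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrolag)
```

## The problem

In sandy coastal aquifers, most anthropogenic nitrogen reaches small
estuaries through groundwater, and groundwater is slow: a parcel near the
watershed divide may need several decades for its septic-system nitrogen to
arrive at the bay. Loading at the bay therefore lags the sources. Two
consequences matter for management. First, a bay can be far from
*equilibrium*: its annual delivered load will keep rising for decades even
with no new development, simply because recently built houses' nitrogen has
not all arrived yet. Second, abatement is similarly lagged — shutting off a
source today does nothing about the *legacy* nitrogen already in transit
underground, which can amount to many years of loading at current rates.

`nitrolag` makes these dynamics explicit with the simplest defensible
machinery: an annual time-step mass accounting over parcels, each carrying
a constant input rate, a fixed attenuation fraction, and a fixed
groundwater travel time.

## Model and assumptions

A parcel contributes nitrogen to groundwater at `raw_load` kg N/yr from its
year built until a scheduled shutoff (or forever). A fraction `attenuation`
is removed en route (denitrification in soils, ponds, wetlands), so the
*delivered rate* is `raw_load * (1 - attenuation)`. Input entering
groundwater in year `y` arrives at the bay in year `y + travel_time`. The
delivered load of a watershed in year `t` is the sum of delivered rates of
all parcels whose input window, lagged by their travel time, covers `t`.

Assumptions worth stating:

- **Piston flow, no dispersion.** Each parcel's nitrogen travels as a plug
  with a single travel time; there is no spreading of an input year's mass
  over several arrival years. With one value per parcel this is the natural
  discretization of an annual model, but it makes step changes sharper than
  reality.
- **Constant rates.** A parcel's load does not vary with occupancy,
  season, or water use; history is a step function (built, optional
  buildout step up, optional shutoff to zero).
- **Attenuation as one multiplicative fraction.** Ponds, wetlands, and
  soil removal are collapsed into a single per-parcel factor rather than a
  chain of landscape features. `attenuate_concentration()` exposes the
  chain arithmetic (`initial * prod(1 - f_i)`) for concentration-style
  what-if calculations, but the engine consumes the combined fraction.
- **Shutoff means elimination.** A source-control upgrade removes the
  parcel's entire delivered contribution from the upgrade year forward,
  not a reduction to an advanced-septic residual. This makes the
  lower-bound scenario a true lower bound.
- **No in-bay processes.** Estuarine residence time, sediment fluxes, and
  atmospheric deposition are outside the model; the output is watershed
  loading at the bay, the quantity regulatory load ceilings target.

## Engine mechanics and numerical choices

The engine (`build_windows()` + `delivered_series()`) runs over calendar
years 1880–2150 by default. Years are plain integers indexed from the
start year; there is no date arithmetic.

- **Arrival rule.** Whether input from year `y` with travel time `tau` first
  arrives in year `y + tau` (`"inclusive"`) or `y + tau + 1` (`"strict"`)
  is a genuine one-year ambiguity in any annual discretization. Both are
  implemented; the default is `inclusive`, the symmetric reading in which a
  zero-travel-time parcel contributes in its build year. The choice shifts
  every series by at most one year and none of the package's diagnostics
  depend on it qualitatively; it is a flag so results are pinned and
  reproducible either way.
- **Travel times are floored** to whole years to match the annual step;
  fractional inputs are legal.
- **Pre-1880 construction is clamped** to the start year rather than
  rejected: such properties exist in real parcel data, and by 1880 (with
  any positive travel time) their loading is at steady state anyway, so
  clamping changes nothing downstream.
- **Open windows are capped** at the end year internally; series never
  extend past the horizon.
- **Accumulation.** `delivered_series()` adds each window's rate over its
  arrival interval with a difference array and prefix sums —
  `O(windows + years x watersheds)`. Prefix sums can leave residuals of
  order 1e-15 where the true load is zero (additions cancelled by
  subtractions); since rates are non-negative the true series is too, and
  negative residuals are clamped to zero. The engine is checked against
  `packet_oracle()`, an independent quadratic enumeration of every
  (window, input-year) packet, at a relative tolerance of 1e-12 — the
  prefix-sum path does not sum the same addends in the same order, so
  bitwise equality is not the right criterion, but 1e-12 is far below any
  physically meaningful difference.

## Scenarios

`scenario_config()` fixes the conventions:

- The "20-year window 2020–2040" is implemented as the twenty event years
  2020–2039 inclusive; endpoint phrasing of such windows is ambiguous by
  one year and this reading makes the quota arithmetic exact.
- **Buildout** draws each buildable parcel's update year uniformly from the
  window; only the *additional* (buildout) load is affected — base loads
  continue, and no source control happens in this scenario.
- **Source control** shuts off all contributing unsewered parcels: a
  uniform random permutation fixes the order, and with `n` parcels over
  `k` years the earliest `n mod k` years take `ceiling(n/k)` upgrades and
  the rest `floor(n/k)`. Nitrogen input before a parcel's shutoff still
  arrives on schedule.
- **Monte Carlo.** Iteration `i` uses sub-seed `seed + i`, so any single
  iteration can be replayed in isolation; the envelope reports per
  watershed-year min/mean/max across iterations. The default iteration
  count is 1000; the package's own verification runs use 25–50 iterations,
  which is ample for envelope-shaped conclusions on synthetic regions.
- **Legacy.** All input stops at the shutoff year (2020); arriving load is
  tallied over 2025–2150. The five-year gap between shutoff and tally
  start is part of the scenario definition being mirrored; because its
  rationale is not obvious, `run_legacy()` also reports a companion total
  from the shutoff year itself (`legacy_mass_from_shutoff_kg`), which is
  the more natural "everything still underground" number.

## Equilibrium and summary metrics

`equilibrium_metrics()` takes the status-quo series and reports, per
watershed, the current load, the maximum future load, their ratio, an
equilibrium flag, and years to equilibrium.

- ε defaults to 0.01: a ratio up to 1.01 counts as "at or near 1". Ratios
  from annual mass accounting are exact, but tiny increases (one small
  parcel still in transit) should not flip a watershed's classification.
  For borderline analyses, sweep ε over {0.001, 0.01, 0.05}.
- Years to equilibrium uses the first crossing of `(1 - ε)` of the future
  maximum rather than the exact argmax, to avoid horizon-edge artifacts
  where the series creeps by float dust near its plateau.
- A zero current load with positive future load yields `ratio = Inf` and
  `in_equilibrium = FALSE`; an all-zero series has ratio 1 by convention.
- `summarize_watersheds()` uses the sample (n − 1) standard deviation, and
  reports `NA` when a watershed has fewer than two *distinct* values —
  mirroring published summary tables that print "-" for watersheds whose
  parcels all share one travel-time band. "Annual maximal load" is the
  maximum of the status-quo series over the full horizon: the load once
  the watershed reaches equilibrium.

## The synthetic generator

`generate_region()` draws attribute-only parcel tables (no geometry) whose
statistical shape matches a region of small coastal estuaries:

- **Parcel counts** log-uniform per watershed — coastal embayment
  watersheds span tiny coves with a handful of parcels to river systems
  with thousands, roughly uniform on the log scale.
- **Year built** normal around 1955 with spread 35 yr, truncated to
  1880–2020: mid-20th-century suburbanization with long tails. Pre-1880
  construction is not generated; the engine's clamp path is exercised by a
  dedicated fixture in the tests instead.
- **Travel times** lognormal about a per-watershed mean drawn uniformly
  from 5–47 yr, with `sdlog = 0.83` (coefficient of variation ≈ 1,
  echoing observed per-watershed sd ≈ mean), capped at 150 yr. The cap
  keeps the heavy tail physical; its effect on the mean is accounted for
  in closed form in the parameter-recovery tests.
- **Loads** lognormal (`meanlog = log 6`, `sdlog = 1` kg N/yr): heavy
  right tail, median ~6 kg N/yr per parcel — a typical single-family
  septic load after landscape-scale averaging, with commercial-scale
  outliers.
- **Attenuation** a three-path mixture {direct 50%, pond 30%,
  pond + wetland 20%} with removal factors {0, 0.3, 0.65}.
- **Sewering** 15% of parcels (these carry zero septic load — their waste
  leaves the watershed); mostly-unsewered is characteristic of the region
  type modelled.
- **Buildout** potential on 12.1% of parcels, with increments drawn from
  the same lognormal as loads.
- **TMDL status** "final" for 60% of watersheds.

`cape_like_preset()` sets 54 watersheds with counts 6–9532. Travel time
and year built are drawn independently; in reality newer construction may
sit systematically farther from shore (longer travel times), so the
generator cannot express cohort-lag correlations — passing tests show the
machinery is correct, not that any particular real region looks like this.

## Verification

The test suite checks the engine against the packet oracle on 200
randomized instances (up to 100 windows, 270-year horizon, both arrival
rules), mass conservation for closed windows, shift equivalence in travel
time, scenario ordering (buildout ≥ status quo ≥ source control,
pointwise, bounded through the Monte Carlo envelopes) on a 54-watershed ×
~200-parcel region with 50 iterations, legacy accounting against both a
per-parcel closed form and the oracle, schedule uniformity by chi-square,
and generator moment recovery at n = 5000 against closed-form truncated /
capped-distribution means at 3 standard errors. `scripts/acceptance.R`
re-runs the headline computations on a full synthetic 54-watershed region
(~10^5 parcels, 25 Monte Carlo iterations) from a command-line seed.

## Known limitations

- Single travel time per parcel; no dispersion, no within-parcel zoning.
- Source-control order is uniformly random; real sewer programs proceed in
  spatially contiguous blocks, which changes *which* watersheds improve
  first but not the region-wide envelope logic.
- Attenuation uncertainty (especially ponds and wetlands) enters only as
  fixed fractions; there is no uncertainty propagation on attenuation.
- The generator is attribute-only and independent across columns; it is a
  test harness and a what-if sandbox, not a calibrated digital twin of any
  real region.
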