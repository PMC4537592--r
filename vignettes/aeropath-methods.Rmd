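---
title: "Methods: from radio detections to wind-mediated flight efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from radio detections to wind-mediated flight efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(aeropath)
```

This vignette records the models `aeropath` fits, the assumptions they
make, the parameters that matter and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and
the numerical choices a maintainer would otherwise have to
reverse-engineer.

## The measurement model

An automated telemetry array quantises a continuous flight into a small
number of event times and a discrete crossing location.

**Event times.** A receiver monitors each radio frequency for a fixed
window per scan cycle (21.6 s on / 43.2 s period at the island
stations; 14 s / 28 s at the coastal ones), so every event time is
known only to within a scan period. Departure and arrival are defined
as the time of maximum signal strength on the passage curve. Ties are
broken toward the earliest time; this matters only for pathological
flat curves.

**False positives.** Coded transmitters pulse at a fixed rate, so the
interval between genuine detections is an integer multiple of the
pulse period. The filter grows runs from the earliest unassigned
detection, absorbing any later detection whose interval from the run's
current tail is within a tolerance (default 0.25 s, configurable; no
tolerance is stated in field protocols) of a positive multiple of the
pulse rate, *skipping* incompatible detections rather than breaking
the run — under a strict consecutive-interval rule a single spurious
hit landing inside a genuine train would orphan the train's first
point. Detections left in runs of one are discarded. The filter is
idempotent.

**Crossing classification.** At a coastal station with two back-to-back
antennas, detection on both antennas places the crossing directly over
the station; detection on one antenna only places it half the
detection range (7.5 km of 15 km; the range is a config constant, not
estimated here) along that antenna's boresight. With the first coastal
station's antennas at 55°/235° this reproduces the three canonical
island-to-coast tracks and, with the published arc-minute coordinates,
the 35.3-km northeast leg to within the rounding of those coordinates
(±0.15 km). All geometry is spherical (haversine, R = 6371 km);
bearings are degrees clockwise from geographic north; coordinates are
decimal degrees, west negative.

**Groundspeed** is track distance over duration. The
distance–duration–speed identity is enforced to 1e−9 relative
tolerance on every segment.

## Wind annotation

Wind tables carry one row per (level, lattice node, time) with speed
and direction. Internally direction is always the heading the air
moves *toward*, so the tailwind component `Vw·cos(β)` is positive when
the wind pushes the bird along its track (`β` = wind heading − track
direction, wrapped to (−180°, 180°]); files using the meteorological
direction-from convention are converted on read (+180°).

Interpolation is inverse-distance weighting on the **u/v vector
components** (never on circular direction, which would average 359°
and 1° to 180°) in the scaled space–time metric
`d = sqrt((Δs/32 km)² + (Δt/3 h)²)`, power 1; the scalings are the
lattice resolutions and both are configurable. Interpolation uses the
16 nearest samples: annotation services interpolate from the
surrounding grid cells, and with power 1 an unbounded sample cloud
would let the sheer mass of far samples drag every value toward the
field mean (we observed exactly this attenuation before restricting
the neighbourhood). `idw_interpolate()` itself defaults to using all
samples so that its documented hand-arithmetic behaviour is exact.

Each segment is annotated at its space–time midpoint (great-circle
spatial midpoint, temporal mean of the event times), one annotation
per level. Pressure levels are labelled by their mean geopotential
height over the table — the "altitude" the scan reports. The level set
is 10 m, 30 m, and 1000→750 mbar in 25-mbar steps: eleven pressure
levels, thirteen in all. (Published descriptions of this level set
give a level count inconsistent with their own span and spacing; we
implement the stated span and spacing.)

## Probing the atmosphere

For each stage and level, flight duration (untransformed, in minutes)
is regressed on the level's tailwind and crosswind. The candidate term
sets are all subsets of {tailwind, crosswind, tailwind×crosswind,
tailwind²} in which the interaction appears only with both main
effects and the quadratic only with the linear tailwind term — eight
models including the null. The quadratic is always in the candidate
set: the original procedure admitted it after a visual linearity
check, which is not reproducible, so inclusion is decided by the same
AICc comparison as everything else. Ocean-stage models carry a nest
random intercept (parent–offspring pairs); coastal models do not
(defaults, overridable). All fits are maximum likelihood, never REML,
so AICc is comparable across fixed-effect structures; `k` counts fixed
effects plus every variance parameter.

A level is *informative* only if its best subset beats the null
(intercept + random effects) by at least 2 AICc units. Across levels,
the informative level with the smallest AICc is selected; exact ties
go to the lowest altitude (a conservative choice; nothing in the
method prefers height). A fit that errors or returns a non-finite
likelihood is flagged and excluded; a zero random-effect variance is
*not* treated as a failure — it is the ML estimate and excluding such
fits would empty the candidate set at telemetry sample sizes.

## The multilevel path model

The analysis table takes, per stage, the wind at that stage's selected
level, then standardizes: continuous variables are z-scored,
groundspeed is log-transformed before scaling, age and stage are 0/1
with juvenile and coast as reference levels (so positive age and stage
coefficients mean "adult" and "ocean" effects), and `tailwind_sq` is
the z-scored square of the z-scored tailwind. Coefficients of these
fits are therefore standardized path coefficients.

The full diagram sends age and stage into tailwind and crosswind, and
age, stage, tailwind, tailwind², crosswind into the response. The
tailwind×crosswind and tailwind×stage interactions ride on the
response's component model as extra fixed terms, not edges: they
change K but no independence claim, so their removal can only lower
the path AICc — the pre-screen that drops them is computed honestly
but is structurally guaranteed to succeed, which mirrors how such
interactions behave under this criterion generally.

**Fisher's C and the basis set.** Every component model is an ML
mixed-effects fit with nest and individual random intercepts. The
d-separation basis set contains one claim per non-adjacent pair of
non-deterministic nodes, excluding exogenous–exogenous pairs (the
age–stage association is left free). The causally later node is
regressed on the union of both nodes' parents plus the other node;
pairs in the same causal layer (tailwind–crosswind) take the
later-declared node as regressand. `tailwind_sq` is a deterministic
companion of tailwind: it never generates claims of its own and
appears only in conditioning sets. Claim p-values are two-sided Wald
tests with a between–within style residual df of `n − p` (`p` = fixed
coefficients in the claim model); exact mixed-model df are not
identified and any of the common approximations changes nothing
qualitative at these sizes. `C = −2 Σ ln p`, χ² with 2·(number of
claims) df; p-values ≤ 0 are clipped to 1e−16 with a warning.

**K accounting.** `K` sums, per endogenous node, fixed effects
(including intercept) + residual variance + one variance per random
intercept. Crucially, a wind component whose incoming edges have all
been eliminated *keeps an intercept-only component model* (it is still
part of the modelled system). This convention reproduces the K column
of the published duration selection table exactly and all but the null
row of the groundspeed table, and it keeps K comparable along an
elimination path. Path-level `AICc = C + 2Kn/(n−K−1)` with `n` = the
number of segment rows.

**Backward elimination** proceeds in the published order — wind-model
edges first, then response edges — greedily: at each step every
currently removable edge is tried, the removal with the lowest
resulting AICc is accepted if it does not raise the AICc by 2 or more,
and the phase ends otherwise. The quadratic edge must leave before the
linear tailwind edge may (the quadratic never appears alone). The
procedure is deterministic, records every distinct model visited, and
closes the table with the null model (the final model minus all
response edges). Note an implication of the two-unit rule worth
knowing: the implicit per-edge retention threshold depends on n and K
through the AICc penalty, so at n = 48 a noise edge survives ~2–4% of
the time, while at n = 200 the same rule is closer to α ≈ 0.12.

## The synthetic world

The generator states one concrete study system and never adapts to
test outcomes:

- **Cohort**: 19 adults, 9 juveniles, 8 parent–offspring nest pairs;
  each bird is also its own "individual" grouping level.
- **Array**: the five stations with the published coordinates,
  boresights, scan cycles and 15-km range. The three island stations
  share the single published island coordinate with sub-km offsets
  (they are used for departure timing only, so their exact layout is
  inert downstream).
- **Winds**: a 32-km/3-h lattice over the study area, 13 levels. Each
  level's wind is its mean vector (slow WSW-ward air near the surface
  strengthening and veering with altitude, so the coastal cruising
  level offers more support) plus an evening-scale synoptic component
  shared by all levels (sd 1 m/s per u/v component), an independent
  per-level per-evening component (sd 4.5 m/s) and lattice micro-noise
  (sd 0.5 m/s). Geopotential heights vary evening to evening (sd 45 m)
  around climatological defaults (~160 m at 1000 mbar, ~820 m at
  925 mbar). **The vertical decorrelation is deliberately stronger
  than a real reanalysis**, calibrated once so that the stated
  recovery property (the altitude scan re-finds the generating level
  per stage in ≥ 90% of seeds at n ≈ 20–28) is identifiable at
  telemetry sample sizes; a green recovery test therefore establishes
  that the inference machinery works, not that real NARR-like fields
  carry this much level-specific information.
- **Departures**: each bird becomes ready on a normally distributed
  evening (mean evening 20, sd 9 — the observed day-to-day spread of
  departure dates) and departs on the first ready evening whose
  tailwind along the ocean track (sampled at the 1000-mbar departure
  level over the island) exceeds its age threshold: +2 m/s for adults,
  −∞ for juveniles. This is the entire age effect; everything
  downstream follows from the winds actually flown in.
- **Flights**: full drift compensation (track held, along-track speed
  `tw + sqrt(Va_h² − cw²)`), airspeed 12 m/s (a configurable
  plausible value — no airspeed estimate exists for this species; the
  published median groundspeeds would in fact suggest ~9–10 m/s).
  Ocean flights use the 1000-mbar winds, coastal flights the 925-mbar
  winds, at the stage midpoint. While the climb penalty is on
  (climb rate 1.5 m/s, within the 1–2 m/s capability of small
  songbirds), the ocean stage is flown at
  `0.75 × sqrt(Va² − climb²)`: the pure vector term alone is a 0.1 m/s
  deficit and cannot produce any detectable stage effect, so the
  0.75 factor stands in for the energetic cost of climb-and-search
  flight over open water — the mechanism hypothesised to slow the
  ocean crossing. Setting `climb_rate_ms = 0` (or the fraction to 1)
  switches the penalty off cleanly, which is what the on/off recovery
  test exercises. Gaussian duration noise (sd 2 min, the scale of
  event-timing error) is added per stage.
- **Detections**: pulses at the 2-s transmitter rate, emitted only
  inside scan-on windows, with a Gaussian signal-strength passage
  curve (sd 150 s) peaked at the true event time; only the peak
  location matters downstream, so the curve shape is a pragmatic
  stand-in. Stations beyond 15 km of the relevant crossing stay
  silent; roughly 20/28 of birds are detected at the far coastal
  station. Spurious detections can be injected at a configured hourly
  rate for filter tests.

Everything is reproducible from (config, seed); identical seeds give
byte-identical CSV output.

What the generator does **not** emulate: RF propagation and antenna
gain patterns, topography, within-night wind evolution at sub-3-h
scales, fuel loads and body-condition effects, partial drift or wind
selection en route, and the vanishing-bearing analysis of departure
directions. Green round-trip tests therefore validate the estimator
chain under the stated world, not the field realism of that world.

## Numerical and interface choices

- Peak-time ties: earliest timestamp. AICc ties across levels: lowest
  altitude. Elimination candidates: deterministic greedy order as
  described.
- Degenerate inputs error early with named messages: zero-variance
  responses or standardization columns, empty detection series,
  non-chronological events, zero-distance tracks, p-values outside
  (0, 1].
- Mixed fits that error entirely are retried without random effects
  (logged via `message()`); this occurred in practice only for
  grouping structures with as many levels as observations.
- Timestamps are UTC everywhere internally (numeric seconds); ISO-8601
  with or without `Z`/`T` parses to UTC. Coordinates accept decimal
  degrees or degree–arcminute strings as printed in field reports.
- `backward_eliminate` memoises component fits and claim tests by
  formula within a run; candidate diagrams share most regressions, and
  the cache cuts runtime roughly in half without changing any number.
- Stochastic test budgets: the acceptance suite runs its full stated
  seed counts (100) using the lightweight per-segment wind generator
  for altitude recovery and the structural-equation generator for path
  recovery; the full detection-level round trip is exercised at a
  handful of seeds in the regular suite because one end-to-end run
  costs a few seconds.

## Known limitations

- Fisher's C values from the original field data are not reproducible
  here (they require the deposited tracks); only the published
  (C, K) → AICc arithmetic and weight columns are.
- The between–within df approximation makes claim p-values slightly
  liberal relative to Kenward–Roger at n ≈ 48; C is affected in the
  second decimal at most in our simulations.
- The altitude probe reports the best *available* level; with strongly
  vertically correlated real winds, adjacent levels can be
  statistically indistinguishable, and the probe's "flight altitude"
  reading should be treated as coarse.
- The K convention for the groundspeed null model differs by one from
  the published table's null row (14 vs 13); the two null models are
  structurally identical and we believe the published value is a
  typo. Printed K values are never asserted in tests.
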