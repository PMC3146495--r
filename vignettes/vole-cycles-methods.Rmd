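---
title: "Methods: simulating vole cycles under predation and fragmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating vole cycles under predation and fragmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(volecycles)
```

## The question and the design

Fennoscandian field-vole populations shift from multiannual 3–5-year
cycles in the north to stable dynamics in the south. Candidate drivers —
the predator community (resident specialists vs generalists), landscape
fragmentation, and the length of the vole breeding season — covary along
that gradient, so their effects cannot be separated in the field.
`volecycles` separates them by simulation: a spatially explicit,
individual-based model of field voles (*Microtus agrestis*) and their
predators is run over a full factorial design,

* predator assembly: generalist-only, specialist-only, mixed;
* fragmentation: the same 1.5% of optimal habitat divided into 1, 9, 25
  or 100 equally sized, equally spaced square patches;
* breeding season: 5 April to 1 September / 1 October / 1 November,

giving 36 scenarios. Each scenario produces replicated annual density
series (census 1 October, after a burn-in), which are then analysed the
way field series are analysed: cycle amplitude (max/min), cycle length
from the autocorrelation function, and direct (AR1) and delayed (AR2)
density dependence from a second-order autoregressive fit of the logged
series. A three-way ANOVA decomposes each endpoint's variance over the
design factors.

## The world model

The landscape is a grid of square cells with two habitat classes.
Optimal habitat supports territories and breeding; matrix habitat can be
crossed but voles starve after `starvation_days` consecutive days there.
Patches are congruent squares centred on a regular lattice (the layout
formula is documented in `build_landscape()`), so the habitat amount is
constant across fragmentation levels. Edges are reflecting; coordinates
are 0-based cells with the origin at bottom-left.

The time step is one day and agents act in a freshly shuffled order each
day: (1) vole behaviour, (2) predator hunts, (3) predator dispersal
checks, (4) mortality. A 365-day calendar is used, with predator spring
reproduction on 1 April, the year-end predator survival evaluation on
31 December and the population census on 1 October.

### Voles

Voles enter the simulation at their mother's nest when weaned at 14
days, with an even sex ratio, and immediately search for a territory —
a square of optimal habitat (females 10 × 10 m, males 20 × 20 m by
default). The search scans candidate sites nearest-first; a site is
blocked when an older same-sex resident would retain more than 50% of
the candidate's area, and settling evicts younger same-sex residents
overlapped by more than half of their own territory (they re-enter
dispersal). Breeding requires a territory and the breeding season. A
female conceives when a mature male's territory overlaps her position,
choosing the closest such male; gestation runs `gestation_days`, litters
are uniform on `litter_min:litter_max`, and the litter weans after 14
days. During the season a mature male whose territory holds no mature
female abandons it and re-assesses (the search prefers sites holding
females) — without this rule, isolated survivors of a deep cycle trough
could never pair again, an artificial Allee effect of the small grid.
Males moving beyond their own territory attempt infanticide on unweaned
litters they encounter, with success declining linearly from
`infanticide_p0` at birth to 0 at weaning. Mortality is by predation,
by starvation (more than `starvation_days` consecutive matrix days) or
at the physiological lifespan limit; every death is attributed to
exactly one cause. Itinerant voles move up to `move_m` per day — a
local random jump on habitat, a directionally persistent walk in the
matrix (dispersal).

### Predators

Two archetypes, parameterised by six quantities each (see
`predator_params()`): a small mustelid-like **specialist** (one
offspring per 5 kills, 90 kills/year to survive, 2500 m² territory,
9.5%/day kill probability, disperses after 5 failure days, 500 m
dispersal) and a fox-like **generalist** (one offspring per 90 kills, 10
kills/year to survive, 6400 m², 4%/day, 20 failure days, 1000 m). Each
day every vole inside a predator's territory is killed independently
with the type's kill efficiency; same-type territories never overlap
(cross-type overlap is allowed). After the failure threshold of zero-kill
days the predator relocates to a random non-overlapping site within its
dispersal range, preferring candidates with detectable prey sign (at
least `prey_sign_threshold` voles) — a giving-up density below which
prey are effectively invisible, which is also what gives remnant voles a
low-density refuge at cycle troughs. Survival is evaluated once per
year on the year's kill count; survivors produce
`min(floor(kills / reproductive_threshold), max_offspring)` offspring
the next spring, each placed in a free territory near the parent or
discarded (recruitment is space-limited). The kill counter carries over
across dispersal moves.

The delayed density dependence characteristic of specialists arises
mechanically: this year's kills determine next spring's recruitment,
and the year-end starvation rule removes predators one year after the
prey decline.

## Desk scale: what is simulated by default

The reference design of the study system is a 10 × 10 km landscape at
1 m resolution, 100 burn-in + 100 sampled years and 20 replicates. That
is far beyond an interactive R session, so the package's defaults are a
scaled-down configuration chosen once:

* 2450 × 2450 m landscape at 10 m cells. With habitat fraction 0.015
  this gives exactly 900 optimal cells, which divides into exact square
  patches (30, 10, 6 and 3 cells on a side) at all four fragmentation
  levels, so habitat area is *exactly* conserved across the design.
* 50 burn-in + 50 sampled years, 5 replicates per scenario.
* The scaled window is treated as open: 2 predators per active type and
  4 voles enter each spring. In the full-scale system the landscape is
  two orders of magnitude larger and local extinction of either player
  is buffered spatially; at desk scale the same openness has to come
  through the boundary. The immigration numbers are negligible against
  peak populations (thousands of voles, >100 predators) but prevent the
  absorbing all-extinct state.

The full-scale design remains expressible: every knob is an argument of
`scenario_config()`.

## Calibration constants

The behavioural rules above are fixed; the quantitative life-history
constants are calibration constants (the organism-level values the
literature supports as ranges rather than points). Defaults:

| constant | default | meaning |
|---|---|---|
| `gestation_days` | 21 | gestation |
| `weaning_days` | 14 | age at weaning/independence |
| `maturity_days` | 60 | age at first breeding |
| `lifespan_days` | 550 | physiological lifespan |
| `starvation_days` | 10 | matrix tolerance |
| `litter_min:litter_max` | 4–6 | litter size |
| territory sides | 10 m (F), 20 m (M) | exclusive same-sex space |
| `search_radius_m` | 50 | daily territory-search radius |
| `move_m` | 80 | daily itinerant displacement |
| `infanticide_p0` | 0.5 | infanticide success on newborns |
| `max_offspring` | 6 | predator litter ceiling |
| `prey_sign_threshold` | 6 | voles needed to register prey sign |

Three of these deserve comment, because the cyclic regime depends on
them and they were set by exploring the model's behaviour at desk scale
(the full-scale system buffers them spatially):

* `maturity_days = 60` (within the field range for *Microtus*): with
  much earlier maturity the vole population rebuilds from a cycle
  trough within a single season and the predator-prey interaction locks
  onto a 3-year period; at 60 days the recovery takes two seasons and
  the modal cycle length is 4 years, with AR1 near zero — the classic
  vole-cycle signature.
* `prey_sign_threshold = 6`: without a giving-up density, dispersing
  predators converge on the last occupied sites and extinguish the
  population at every trough; with a very high threshold troughs are
  shallow and the delayed signal weakens.
* `max_offspring = 6` (a mustelid/fox litter): the raw kill-count rule
  would allow >100 offspring per specialist after a peak year, which
  annihilates the prey in one season.

These are biological constants of the simulated system, not fitting
parameters of the analysis stack; all are exposed as arguments.

## The analysis stack

* `log_density()` — natural log; series containing zeros (extinction
  replicates) are offset by the smallest positive value and flagged.
* `amplitude()` — max/min of the raw density series; infinite (and
  flagged) for extinction replicates.
* `acf_values()` — the standard biased autocovariance estimator
  normalised by lag 0 (as `acf()`); `ci_halfwidth(n, alpha)` gives the
  white-noise band \(z_{1-\alpha/2}/\sqrt{n}\).
* `cycle_length()` — the lag of the second positive significant ACF
  maximum, counting lag 0 as the first: the smallest lag \(L \ge 2\)
  with a significant local maximum. Stability requires another positive
  significant local maximum within one lag of \(2L\); otherwise (and
  when `max_lag` cannot reach \(2L\)) the series is classed non-cyclic
  and 0 is returned. Local maxima are strict, with plateau ties broken
  toward the smaller lag. Default `max_lag = min(n/4, 25)`.
* `fit_ar2()` — OLS of \(x_t\) on \((x_{t-1}, x_{t-2})\) with
  intercept on the logged series. AR1 and AR2 are the raw slopes by
  default; `convention = "royama"` reports the direct coefficient on
  the growth-rate scale (\(\phi_1 - 1\)). Raw slopes are the scale on
  which a 4-year cycle has AR1 near 0 and strongly negative AR2.
* `vole_endpoints()` — the per-replicate endpoint table;
  `anova_decompose()` — balanced three-way factorial ANOVA with all
  interactions, reporting per source the Minitab-style adjusted
  contribution \((SS - df \cdot MSE)/SS_{total} \times 100\), floored
  at zero.

The synthetic generators (`gen_ar2()`, `gen_periodic()`, `gen_white()`,
`gen_extinction()`, `gen_grid_fixture()`) produce series and factorial
tables with known ground truth so that every analysis operation is
validated independently of the simulator; they exponentiate a latent
log-scale process so the pipeline's log transform is exercised.

## Predation diagnostics

`sim_diagnostics()` summarises per-predator annual hunting records:
days without a successful kill, kills, and vole-exposure days (voles
standing inside a predator's territory, per day). Two definitional
points, both consequences of the engine's mechanics:

* kills per vole-exposure-day equals the Bernoulli kill efficiency by
  construction, so the rate that responds to fragmentation is the
  hunting *yield*, kills per predator-day (`kills_per_day`);
* the desk-scale window produces a proportionally large population of
  transient predators that never meet a vole (spring recruits placed in
  matrix, dead by year end); their zero-kill days dominate the mean in
  every scenario alike. Fragmentation comparisons therefore condition
  on *established* predators — `min_kills` at the type's survival
  threshold — matching the natural reading of a resident predator's
  hunting record.

## What the desk-scale runs do and do not show

With default settings the package reproduces the study system's
qualitative structure: specialist-driven 4-year cycles with AR2 below
−0.7 at low fragmentation, non-cyclic dynamics under generalists alone,
declining cycle amplitude with fragmentation, loss of cycling in the
100-patch landscape, and more failure days/lower hunting yield for
specialists in fragmented landscapes.

Two full-scale quantities are structurally out of reach of the 20×
spatial scale-down. First, a desk-scale habitat patch in the 100-patch
landscape (30 × 30 m) is smaller than a single specialist territory, so
the full-scale mechanism of several predators crowding one patch cannot
occur, and the standing fraction of unoccupied patches at the 1 October
census stays far below the full-scale figure: predator pressure comes in
landscape-synchronised waves (the year-end survival rule is global) with
full vole recolonisation between waves. Second, and for the same reason,
the suppression of mean population size by specialists is milder at desk
scale than at full scale. Both are reported as measured.

Passing tests validate the behavioural rules, the analysis stack and the
qualitative factorial structure; they do not certify that the simulator
predicts real Fennoscandian time series, and the synthetic data share
none of the spatial autocorrelation of real landscapes.

## Numerical choices

* One RNG stream per replicate (xoshiro256++ seeded by splitmix64 from
  the child seed), so replicates are independent and runs replay
  bit-identically for a given `(config, master_seed)`; child seeds are
  a deterministic integer function of (master seed, scenario id,
  replicate), all below 2^31.
* Ties in territory search are broken nearest-first in a fixed spiral
  order; mate choice ties go to the first candidate in scan order.
* Predator candidate sites: 12 uniform draws in the Chebyshev square of
  the dispersal radius; placement tries 12 (recruits) or 200
  (immigrants) times before giving up.
* Degenerate analysis inputs are rejected with errors: series shorter
  than 20 (cycle length) or 10 (AR fit), zero-variance series, zeros
  without `zero_offset`.
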