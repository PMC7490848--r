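---
title: "Methods: a super-individual mackerel simulator on a synthetic seascape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a super-individual mackerel simulator on a synthetic seascape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scombrus)
```

## The model in brief

`scombrus` simulates the western spawning component of the Northeast
Atlantic mackerel stock as a population of super-individuals (SIs): each
agent carries the state of one representative fish — length, structural
mass, lipid reserve, gonad mass, life stage, position, migration and
feeding flags — plus an abundance counter for the number of identical
individuals it stands for. Mortality scales abundance; an SI below one
individual is removed. A constant number of SIs (`n_cohort` per year,
fifteen age classes, user-chosen in multiples of 1050 SIs) keeps the agent
count roughly constant while abundances vary with egg production and
mortality.

The seascape is a grid of square cells (default 60 km edge — the source
grid spacing is ambiguous between cell area and edge length, so the edge
is configurable) carrying phytoplankton density (g m⁻²), SST (°C),
photoperiod (fraction of 24 h), zonal/meridional currents (km h⁻¹) and
bathymetry. Phytoplankton and SST refresh every 10 days; photoperiod and
currents monthly (photoperiod values correspond to the 15th of the month);
fishing mortality-at-age annually with monthly catch fractions. The model
advances in 5-day steps through a fixed 12-process order (forcing,
mortality, movement, energy budget, stage progression, reproduction,
recruitment, recording); an SI killed by mortality never moves in the same
step.

## Annual cycle

Adults depart on the spawning migration on February 1st (also the
maturation census: juveniles at or above L_mat = 26.2 cm all mature that
day), compute potential fecundity on March 1st, spawn five batches at
12-day intervals over a 60-day season while hopping northwards through the
10–14 °C window, migrate to the feeding grounds on May 1st, forage by
gradient area search (GAS) over summer, depart to overwinter on October
1st and fast from November 1st until after the next spawning season.
Migrations descend a breadth-first-search hop-count field computed over
ocean cells with 4-neighbour adjacency (land impassable; the spawning and
feeding legs are additionally constrained to the −550 to −50 m shelf-edge
corridor). The feeding migration ends at a stop distance drawn uniformly
on [0, 10] patches from the target — the source behaviour is "a randomly
selected distance" without a distribution, so the uniform is our choice
and the maximum is configurable.

## Energy budget

Ingestion is a Beddington–DeAngelis response scaled by body surface area
(M^(2/3)) and relative Arrhenius temperature dependence; assimilation
efficiency is 0.95. Maintenance is the standard metabolic rate, replaced
(not augmented) by the active rate on migration or foraging days — the
active rate is defined as what maintenance "is increased to", so
effective maintenance is max(SMR, AMR); the AMR speed argument is the
minimum swimming speed on migration days and the realised daily
displacement speed on GAS days. Deficits are drawn from lipid reserves;
surpluses pay growth first (for feeding stages), then are stored as lipid
after a synthesis charge of E_sl per gram, capped at the maximum reserve.
For spawning adults — who are fasting — batch provisioning draws directly
on reserves and outranks growth (which is zero anyway outside feeding).
Growth is funded only from the current step's surplus, never from
reserves: reserves exist for maintenance, overwintering and reproduction.

Three choices deserve flagging:

- **E_max is applied literally as a mass proportion**: the reserve cap is
  a lipid mass of 0.78 × structural mass, expressed in kJ through the
  lipid energy density. The source prose does not disambiguate energy
  versus mass proportion.
- **Both Arrhenius forms are kept exactly as published**: the metabolic
  rates use the absolute form e^(−E_a/KT); ingestion, the profitability
  cue and growth use the relative form normalised at T_ref.
- **Males pay an equal reproductive cost** (provisioning computed from
  their own length) but contribute no eggs; fecundity is female-only and
  the sex ratio is 1:1, matching the stated equal investment of the sexes.

Every SI's step closes an explicit ledger: assimilated energy equals
maintenance + growth cost + lipid-synthesis cost + discarded overflow +
reserve change − unmet demand. The largest absolute residual across a run
is reported in the outputs and asserted below 10⁻⁹ kJ in the tests.

## Growth integration

The growth-rate equations are per-day rates: Gompertz
(k₁ A L ln(L₁/L)) before the phase-switch age of 240 days and von
Bertalanffy (k A (L∞ − L), doubled k for adults, which grow only while
feeding) afterwards. Rather than accumulating forward-Euler error over
5-day steps, each step applies the exact closed-form solution of the
corresponding ODE with the Arrhenius-scaled rate constant held fixed over
the step. Simulated trajectories under constant temperature and unlimited
food therefore reproduce the analytic length-at-age curves to numerical
precision, and the published rate equations are recovered exactly as the
instantaneous derivatives. The von Bertalanffy shift t₀ is not published;
its default makes the adult curve continuous with the first-season
Gompertz curve at 240 days (t₀ ≈ −492 days), which also supplies
realistic initialisation lengths-at-age.

## Parameters

All rate constants are stored per day with the step length (5 days) held
in the parameter set; `per_step()` makes the conversion explicit. Energies
are kJ, masses g wet weight, lengths cm, speeds km h⁻¹; temperatures are
Kelvin inside metabolic equations and °C for behavioural thresholds. The
published constants (Table of `default_parameters()`) are taken as given —
including the attribution quirk that the two metabolic normalisers trace
to each other's references; the values are used exactly as printed.
Constants the source leaves unhoused get documented, configurable
defaults:

| constant | default | rationale |
|---|---|---|
| T_ref | 283.15 K | mid spawning window (10 °C); the reference is stated to be arbitrary |
| a_w, b_w | 0.0049, 3.17 | typical scombrid length–weight allometry |
| M_0 | 0.001 g | egg wet mass |
| b_int | 12 d | fixed by the 60-day season ÷ 5 batches |
| growth switch | 240 d | end of the first growing season |
| cannibalism cutoff | 0.33 cm | as printed; restricts prey to eggs and yolk-sac larvae (possibly a typo for a relative rule — kept literal, configurable) |

## Movement details

The GAS model runs five daily sub-steps per time step in continuous
space. Each day: a directed half-day (keep yesterday's heading if the
current location improved, else step along the central-difference gradient
of the profitability cue at speed V_min(1 + ε), ε ~ U(0,1)); a random
half-day in a direction drawn uniformly on [−90°, +90°] about due north —
the source only says "not southward", so this convention (due east/west
included) is ours; then current advection over 24 h. Cold (< 7 °C) or
land targets cancel the directed component, reverse the random heading,
and displacement by currents is abandoned for the centroid of the nearest
suitable patch. The profitability cue is computed once per step (density
D is a per-step quantity); positions move within the frozen cue during
the five sub-steps. Heading memory is one day, initialised from the
gradient on the first feeding day; with a flat cue and no heading the
directed component is zero rather than a fabricated direction.

Ties in the migration minimum-R choice and in all random-walk and
neighbour selections break uniformly at random. If no patch is reachable
(e.g. an isolated corner), the SI stays put — a valid, logged state, not
an error.

## Recruitment, spin-up and the calendar

Recruitment is emergent by default: the season's egg production is divided
equally among the year's `n_cohort` egg SIs, created at the batch events
at spawners' locations; recruitment is censused as age-0 survivors on
December 31st. During the ten-year spin-up, recruitment is instead forced:
cohorts enter at year end with lengths L₁ − 3ε ∈ (17, 20] cm, and
emergent egg SIs are suppressed (running both would double-count young of
the year; the source fixes the annual entry count, not the within-season
timing). The optional Ricker mode replaces the egg and larval stages
entirely; its SST-covariate form R = αS e^(−βS + γT̄) requires
user-supplied coefficients — the fitted values are deliberately not
defaults. The calendar ignores leap days (365-day years, 73 steps) so that
the 10-day and 5-day cadences never drift; month-bound events fire in the
step containing the month start, and fishing is apportioned per day
(annual F × month fraction ÷ days in month), which sums exactly to the
annual rate.

## The synthetic seascape

`generate_synthetic_forcing()` emulates the features of the real forcing
that the behavioural sub-models need: a meridional SST gradient
(14 °C mean in the south, −0.3 °C per degree latitude) with a 3.5 °C
seasonal cycle peaking on day 220, which opens a 10–14 °C spawning band in
the south in early March and walks it northwards through spring; a
phytoplankton bloom (amplitude 8 g m⁻², 35-day width) peaking later and
stronger at higher latitudes, so the feeding migration is rewarded;
photoperiod from the astronomical day length at each cell's latitude; and
weak sinusoidal currents (0.05 km h⁻¹). The bathymetry is a deep basin, a
two-cell shelf-edge corridor spanning the meridional extent, a shallow
shelf (nursery) band and an eastern landmass; destinations sit at the
corridor's southern end (spawning) and at its opening into the northern
seas (feeding), with the overwintering box just north of the latter.

What the generator does *not* emulate matters for interpreting green
tests: there is no interannual variability, no cloud gaps or regridding
artefacts, no mesoscale structure in currents, no coastline complexity,
and the bloom/SST fields are smooth and noise-perturbed rather than
patchy. Passing tests demonstrate that the mechanisms are implemented
correctly and interact as specified — not that the model is calibrated or
validated against the real stock. The published headline fits (assessment
SSB, weight-at-age, survey sensitivity/specificity) depend on
undistributed assessment and survey data and are out of scope here; the
calibration and validation machinery is instead exercised by
parameter-recovery and oracle tests on the synthetic world.

## Calibration and validation machinery

`abc_calibrate()` implements plain rejection ABC: uniform priors, seeded
draws (optionally Latin-hypercube at small n), a cost equal to the sum
over datasets of squared deviations divided by each dataset's observation
variance — the source says only that deviations are "normalised" across
units, so variance normalisation is our declared choice, swappable by
pre-scaling targets — and acceptance of the best fraction.
`optimise_threshold()` scans the finite set of observed density values
(plus one value above the maximum, the all-absent rule) exhaustively, so
its optimum is global on that set by construction; the default objective
is Youden's J, with accuracy selectable. A cell counts as present at
densities at or above the threshold.

## Problem sizes and determinism

The shipped tests run the full simulator at deliberately small scale: a
30 × 30 or 40 × 40 grid, 105 SIs (the `test_scale` flag relaxes the
1050-multiple rule, which stays strict in production), two-year spin-ups
and two-to-three-year main phases; the ABC recovery experiment uses 200
draws at 5% acceptance on a 20 × 20 world, and the acceptance script runs
the full ten-year spin-up at the production count of 2100 SIs. One master
seed drives initialisation, forcing generation (via a derived seed) and
the per-step dynamics, so identical configurations replay bit for bit.

## Known limitations

- Eggs and larvae do not drift: young stay at the spawning location until
  they can move as juveniles, since currents act only on adult summer
  movement. Juveniles born outside the nursery area walk only if nursery
  patches are within reach; otherwise they remain where they hatched.
- Only adult summer movement is Lagrangian; all other movement is
  patch-discrete.
- Straying between spawning components is not represented.
- Temperature-dependent egg development is deliberately collapsed to a
  constant five days with constant early mortality.
- Fishing is spatially uniform within an age class.
- Larvae are exempt from starvation removal until their first successful
  feeding; the source is silent on larval reserves, and without the
  exemption every newly hatched cohort would be culled before first
  feeding.
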