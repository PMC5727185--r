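---
title: "An individual-based model of dental plaque dysbiosis under pulsed sugar intake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based model of dental plaque dysbiosis under pulsed sugar intake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Dental caries is driven by dietary sugars: repeated acid challenges select
for acid-producing, acid-tolerating (aciduric) bacteria within supragingival
plaque, and once the enamel-surface pH regularly drops below the critical
value 5.5, net demineralisation begins. Whether the *frequency* of sugar
intake or the *total daily amount* is the stronger determinant is a
long-standing question with direct consequences for dietary guidance.
`plaquesim` implements an individual-based (agent-based) reaction–diffusion
model of a small patch of plaque that makes the two factors independently
tunable: a glucose intake schedule is specified by a total daily amount (in
g/L/d) and a number of 15-minute pulses per day, and the simulation reports
the minimum pH at the enamel surface and the aciduric fraction of the
community — the model's cariogenicity readouts.

## Model structure

**Geometry.** A rectangular domain of `box_x × box_y` µm (default
500 × 500, laterally periodic) extends from the enamel plane at z = 0
through a biofilm compartment of thickness `h_plaque` (250 µm) and a
stagnant saliva layer `h_saliva` (250 µm) to the saliva–air interface.
Particles are spherical cell aggregates (10 µm diameter at division)
attached to the growing film; any particle whose centre exceeds `h_plaque`
is removed after each growth phase, so film thickness is capped and total
particle number fluctuates about a balance of growth, death and pruning.
This makes space itself a contested resource: one lineage can only expand
at the expense of the other.

**Two functional types.** The community is reduced to two populations
defined by function rather than taxonomy: non-aciduric commensals (NA,
glycolysis optimum pH 7, glucose half-saturation 0.1 g/L) and aciduric
cariogens (A, optimum pH 5, half-saturation 0.4 g/L). Both are acidogenic.
Runs start from a lattice filling the biofilm compartment with 5% A
uniformly mixed.

**Glycolysis.** Particle *i* of mass *m<sub>i</sub>* converts a carbon
source at concentration [Gl] to lactic acid at rate

r<sub>i</sub> = m<sub>i</sub> µ<sub>max</sub> · [Gl]/([Gl] + K<sup>Gl</sup>) ·
4[H⁺]K<sup>acid</sup>/([H⁺] + K<sup>acid</sup>)²,

a Monod saturation factor times a pH-inhibition factor that is exactly 1 at
[H⁺] = K<sup>acid</sup> and falls off symmetrically in log[H⁺] on either
side. The rate is evaluated separately for dietary glucose and for the
stored-polyglucose background and the two are added. Growth is tied to
metabolism, dm/dt = Y r<sub>i</sub> with Y = 0.1, plus inert EPS produced
at Y<sup>EPS</sup> = 0.04; at the division mass a particle splits into two
equal daughters placed tangentially in a uniformly random direction.

**Two carbon sources.** Dietary glucose enters as a Dirichlet boundary
value at the saliva–air interface: the pulse concentration
`total / (frequency × duration)` during each 15-minute pulse and zero
otherwise, so that doubling the frequency at fixed total halves each pulse.
Stored polyglucose is modelled as a constant, uniform, never-depleted
background equal to 1% of the total daily amount — the low-level feast
residue that keeps metabolism (and acid production) ticking between pulses.

**Acid, pH and death.** Lactate diffuses like glucose and is cleared by a
zero-Dirichlet condition at the saliva–air interface. pH follows from
total lactate by charge balance in a medium resting at pH 7 that contains a
monoprotic salivary buffer (30 mmol/L, pKa 6.8) and lactic acid (pKa 3.86);
the map is strictly decreasing in lactate and anchored at the baseline.
Death is a stochastic hazard proportional to [H⁺],
r<sup>death</sup> = r<sup>death</sup><sub>type</sub> · [H⁺]/10⁻⁷, with the
neutral-pH rates 3 × 10⁻³/h (A) and 6 × 10⁻³/h (NA) encoding A's greater
acid tolerance. Dead particles are removed without recycling.

**Adaptation.** Optionally, each particle's acidity optimum relaxes toward
the local environment, dK<sup>acid</sup>/dt = M([H⁺] − K<sup>acid</sup>),
integrated exactly per step. The change is physiological, not heritable:
daughters revert to the type's initial optimum. `M = 0` (the default)
disables it; 10⁻²/h and 3 × 10⁻²/h are the calibrated settings explored by
`adaptation_calibration()`, which reproduces the planktonic protocol (hold
a low pH for a set time with death disabled, restore pH 7, compare acid
production against an unadapted control).

**Mechanics.** After growth, death and division the sphere packing is
relaxed by shoving: every overlapping pair is displaced symmetrically along
its centre line by half the overlap (minimum-image laterally, hard floor at
the enamel), sweeping until the largest overlap is below 1% of the mean
radius or 100 sweeps are reached, in which case the residual is recorded
and the run continues. In a densely jammed film the residual is often
non-zero; positions are the only state mechanics may touch.

## Numerical scheme

The engine is operator-split. Each biology macro-step (1 min inside a
±30 min window around each pulse, 10 min otherwise, truncated to land
exactly on pulse and window edges):

1. samples glucose, polyglucose and H⁺ at particle centres (containing
   cell by default, trilinear optional);
2. deposits per-particle uptake and acid production onto the grid
   (conservative to machine precision) and advances both solute fields by
   backward-Euler diffusion on the 7-point Laplacian with explicit,
   frozen reactions — substeps of at most 1 min, any substep changing a
   cell by more than 50% relative being recursively halved; the sparse
   Cholesky factor of each (I − Δt D ∇²) operator is cached per Δt;
3. grows, adapts, kills, divides, shoves and prunes, in that fixed order;
4. records observables (enamel-layer mean pH via an interpolation table
   built once per run from the exact charge-balance solver; table error is
   well below 10⁻³ pH units).

Negative concentrations produced by a sink exceeding local supply are
clipped to zero and the clipped mass is logged and reported in the
step's mass ledger, which closes to a relative 10⁻⁸ each step. A single
global R random stream drives initial typing, death, and division
directions, so a (schedule, parameters, seed) triple reproduces a
trajectory bit for bit; replicate *r* of a sweep uses `base_seed + r − 1`.

Degenerate inputs are handled explicitly: an empty population is a fixed
point of every population operation; extinction ends a run early with
status `"extinct"`; coincident sphere centres are split deterministically
along z; a measurement window without a pulse is a contract error, not a
silent zero.

## Choices made where the design was open

* **Diffusivities** are uniform over biofilm and saliva (gradients arise
  from uptake, not hindered diffusion): 6.7 × 10⁻¹⁰ m²/s for glucose and
  1.0 × 10⁻⁹ m²/s for lactate, standard aqueous values; both configurable.
* **Acid clearance** is the minimal mechanism consistent with neglecting
  saliva flow: a zero-lactate Dirichlet sink at the saliva–air interface.
* **pH chemistry** uses charge balance with a phosphate-like buffer
  (30 mmol/L, pKa 6.8) rather than a tabulated empirical dissociation
  curve; the constants are exposed in the configuration.
* **Particle scale and acid-production calibration**: aggregates are 10 µm
  in diameter at the division mass. Neither the aggregate mass nor the
  biomass density is observable directly, and together they set the
  film's volumetric acid production, to which every pH readout is
  sensitive. The density default (40 g/L, a dry-biomass scale value, with
  the division mass scaled to keep the 10 µm diameter) was calibrated
  once, on the full-depth geometry at 6 pulses/day, so that the enamel pH
  spans the high-4s to high-5s between 10 and 20 g/L/d with a famine
  plateau near 6 — the operating range the model is meant to occupy. A
  wet-biomass density (≈ 200 g/L) overproduces acid roughly four-fold and
  pins the famine-phase enamel pH near 4.3 at every physiological intake;
  increasing the buffer capacity cannot compensate, because the mismatch
  is in production, not chemistry. Daughters take half the mother's mass
  each (the symmetric reading of an equal-mass split).
* **EPS** is inert attached mass: it adds volume (packing, radius) but
  never metabolises or divides independently.
* **Stoichiometry**: 2 mol lactate per mol glucose (homolactic
  fermentation), configurable.
* **First-pulse phase** is t = 0; pulses are equally spaced. The schedule
  accepts non-integer frequencies so critical-frequency scans can
  interpolate.
* **Measurement convention**: "minimum pH at 60 days" means the minimum of
  the enamel-layer mean pH over the final inter-pulse period (which
  contains exactly one pulse); the recovered famine plateau is read over
  the last quarter of each inter-pulse interval.
* **Uptake capping**: rather than pre-limiting uptake to locally available
  glucose, the solver clips negative concentrations and logs the clipped
  mass, keeping the mass ledger exact.

## What the presets emulate, and what tests can show

The `"full"` preset is the full-scale parameterisation above; mapping the
complete frequency × amount plane on it is an overnight computation
(`scripts/full_suite.R`). Two reduced presets are the package's own study
conditions for testing. `"patch"` keeps the full 250 + 250 µm depth — and
with it the mass-transfer limitation that makes infrequent, concentrated
pulses less dangerous than frequent dilute ones — on a 100 × 100 µm
lateral patch (2500 particles); lateral extent mostly buys statistics, so
this is the faithful scale-down for cariogenicity readouts. `"desk"`
additionally thins the film to 100 µm under 50 µm of saliva (10³
particles); its short clearance path makes it roughly an order of
magnitude less acidic than full depth, which is fine for engine-level
properties but not for pH quantities.

The test suite runs patch simulations of 0.5–1 simulated day and desk
simulations of up to 2 days. These demonstrate the mechanisms — the
Stephan-like pH dip and recovery, reversal of selection at pulse edges,
glucose depletion toward the enamel, enrichment of aciduric particles at
depth, monotone response to the total amount, stationary particle counts,
and dt-convergence — and check the headline quantitative targets of the
full-scale study in scaled-down form only. Quantities that mature over
tens of days through composition change (the full three-class map, the
critical frequency, the slow mature-film doubling time) are not reachable
in day-scale runs and are expected to deviate there; the overnight suite
exists for exactly that reason. Passing desk/patch tests cannot certify
real-plaque quantitative accuracy either: the model inherits the usual
idealisations (parameters from planktonic experiments, two functional
types, aggregates as units, no saliva flow or enamel chemistry, a
constant polyglucose pool).

## Known limitations

Single acid species and monoprotic buffer (no bicarbonate/CO₂); no
spatially varying diffusivity; no detachment by shear, only height
pruning; shoving may leave a logged residual overlap in jammed packings;
the dt-halving guard controls splitting error empirically rather than by a
formal estimate; full-scale runs are expensive in plain R (hours per
60-day trajectory), which is why the desk preset exists.

## A short session

```{r}
library(plaquesim)

params <- preset_params("desk")
sched  <- intake_schedule(total_amount = 20, frequency = 6)  # 13.3 g/L pulses

sim <- plaque_sim(sched, params, days = 2, seed = 1)
summary(sim)
plot(sim)

depth_profiles(sim, n_bins = 15)        # glucose / pH / composition vs depth
min_enamel_ph(sim, c(44, 48.2))         # cariogenicity metric, final window

sw <- run_sweep(totals = c(10, 15, 20), frequencies = c(4, 7, 10, 13),
                days = 1, replicates = 2, base_seed = 1, params = params)
plot(sw)
critical_frequency(sw, total = 15)
```
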