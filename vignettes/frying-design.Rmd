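---
title: "Methods: multi-objective frying design with frypareto"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-objective frying design with frypareto}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(frypareto)
```

## The design problem

Frying a potato slice is a trade-off. Hotter or longer treatments give the
yellow colour consumers prefer, but they also dry the slice and drive the
Maillard chemistry that produces acrylamide, a probable carcinogen with a
recommended ceiling of 50 µg/kg in fried potato products. frypareto frames
the choice of an isothermal treatment (frying time *t*, oil temperature *T*)
as a constrained bi-objective optimization:

* minimise final acrylamide (µg/kg),
* maximise final yellowness *b* (CIE-Lab),
* subject to *t* ∈ [0.1, 10] min, *T* ∈ [120, 200] °C, and final moisture
  *X* ∈ [2, 4] (a crispness proxy; the constraint is evaluated at the end of
  the process only, not along the path).

The result is not a single optimum but a Pareto front, plus two analyses of
its structure: the detection of practically interchangeable operating points,
and the propagation of kinetic-parameter uncertainty to an ensemble of
fronts.

## Models and assumptions

### Acrylamide: the Maillard reaction network

Acrylamide formation is modelled by five coupled ODEs in species
concentrations (mmol/L): glucose isomerises to fructose (K2); glucose and
fructose condense with asparagine to a Schiff base (K1, K3, bimolecular);
the Schiff base decays either to acrylamide (K4) or to melanoidins (K5);
acrylamide itself is eliminated (K6). The initial composition is the Agria
potato without pretreatment: 4.12 mmol/L glucose, 2.95 mmol/L fructose,
11.77 mmol/L asparagine, with no Schiff base or acrylamide present in the
raw slice. Two consequences follow directly from the structure and are
enforced as tested invariants: asparagine is non-increasing (both its rate
terms consume it), and acrylamide is non-decreasing whenever K6 vanishes.

Key assumptions: the slice is isothermal at the oil temperature (no internal
temperature gradient), the treatment is at constant temperature, and
melanoidins, acetic acid and other side products are not tracked (they do
not feed back into the five modelled species).

Each rate constant is parameterised as ln *K*(*T*) = ln *k*<sub>ref</sub> +
*a·g*(*T*). The default transform *g* is Arrhenius-type,
1/(T<sub>ref</sub>+273.15) − 1/(T+273.15), so *a* has Eₐ/R semantics
(Kelvin); a plain log-linear transform *g* = *T* − T<sub>ref</sub> (slope
per °C) is selectable per constant. Published values of K1–K6 and their
confidence intervals belong to the primary kinetics literature and are
supplied through a validated YAML/JSON config; the package itself ships no
literature numbers.

### Units at the reporting boundary

The ODE state stays in mmol/L throughout; conversion to µg/kg happens only
in `acrylamide_mass_fraction()`. The default factor, 71,080 µg/kg per
mmol/L, assumes acrylamide's molar mass of 71.08 g/mol and one litre of
reacting volume per kilogram of product. No source states the exact
density/basis conversion, so this is an explicit, documented assumption and
a plain argument anyone can override.

### Quality: first-order colour and drying kinetics

Yellowness and moisture each relax exponentially toward a
temperature-dependent equilibrium, with rate and equilibrium given by
power laws in reduced temperature *T*/170 (°C, no Kelvin conversion — the
correlations are used exactly as fitted) and reduced thickness *d*/10 (mm):

* K_b = 0.12 (T/170)^2.49 (d/10)^−0.44, b_e = 36.2 (T/170)^1.012 (d/10)^−0.2
* X_e = 0.54 (T/170)^−3.63 (d/10)^0.89, K_X = 0.78 (T/170)^1.61 (d/10)^−2.27

with defaults *d* = 15 mm, *b₀* = 22.6, *X₀* = 3.9 (untreated slices).
Moisture is kept on the single scale on which the constraint interval is
[2, 4]; no percent/dry-basis conversion is applied. Because both laws are
invertible in closed form, `time_to_yellowness()` and `time_to_moisture()`
return exact treatment times (or `NA` when the target lies beyond the
equilibrium at that temperature) — these inversions carry the whole
optimization. Since *X₀* = 3.9 < 4 and moisture only falls, the upper
moisture bound can never become active; only the X = 2 boundary shapes the
feasible set.

## The two solvers

### Complete level-curve search

For each yellowness level *b\** on a grid across the attainable interval,
the level set S_b\* is sampled by temperature: each sampled *T* contributes
at most one time via the colour-law inversion, kept if it lies in the
decision box with feasible moisture. Minimising acrylamide over each level
set yields one front point per level. Implementation detail: all candidate
times that share a temperature are evaluated from a *single* network
trajectory (the ODE solution at fixed *T* passes through every level
crossing), so the search costs one solve per sampled temperature rather
than one per (level, temperature) pair — a ~400× saving at default
resolution with identical results. Defaults: *b\** step 0.01, temperature
step 0.05 °C. Ties in acrylamide within 1e-9 µg/kg break toward lower
temperature, then lower time — the milder process.

### NSGA-II

The genetic solver is the canonical elitist NSGA-II, written in the package:
real-coded (t, T) genes, simulated binary crossover (index 15, probability
0.9), polynomial mutation (index 20, probability 0.5 per gene), binary
tournament and environmental selection under constrained domination
(feasible beats infeasible; infeasible compare by total moisture violation
max(0, 2−X) + max(0, X−4)), crowding-distance truncation. Defaults are
population 100 for 200 generations. One refinement: individuals whose
objective vectors exactly duplicate another's receive zero crowding
distance, so duplicates are preferentially discarded — boundary points keep
their infinite distance. The two solvers are cross-validated in the test
suite: the NSGA-II front must lie within 0.02 of the complete-search front
in normalised objective space.

An honest caveat on elitism: with crowding-distance truncation the best
point of an *interior* yellowness bin can in principle be displaced; what
the algorithm guarantees — and what the tests assert — is that the global
best of each objective never worsens across generations.

## Equivalent operating points

Two treatments are quasi-equivalent when their objectives agree within 0.01
(applied to acrylamide in µg/kg and to yellowness, as a conjunction when
both are available) while the treatments differ by at least 1 °C *and*
0.2 min. Groups are built by single linkage over the pairwise relation and
then pruned — greedily dropping the member with the most violated pairs,
ties toward higher yellowness — until every remaining pair is valid, which
makes the output deterministic and independent of input order. The
constructor accepts a zero objective tolerance (useful as a degenerate
check: continuously evaluated points then never group), while the
separation thresholds must stay positive.

`equivalence_curve()` traces the locus of treatments delivering a target
outcome and marks a maximal pairwise-separated subset by a greedy sweep in
temperature order. The number of such members shrinks as the target
yellowness rises: the objective surfaces are flat at mild conditions and
steep near the hot boundary, where the active X = 2 constraint pins an
essentially unique point.

## Monte-Carlo uncertainty propagation

Each of the six rate constants is drawn independently from a normal centred
on its nominal value with its configured standard deviation,
*resampled until positive* (rejection, not clipping — clipping would put a
point mass at zero). When a draw's activation uncertainty is configured it
is drawn too, unconstrained in sign. A guard refuses configurations whose
standard deviation puts nearly half the normal mass below zero, where
positivity rejection stops being meaningful. No correlation between
constants is assumed (none is published); a correlation input would be a
straightforward extension.

Per draw, the bi-objective problem is re-solved — by NSGA-II with a seed
derived as base seed + draw index (the default, matching how large
ensembles are produced in practice) or by the deterministic complete search
(useful for coarse sweeps, and for the exact zero-variance collapse check,
which the genetic solver cannot satisfy bit-for-bit because each draw
receives a fresh seed). The nominal front is always computed by the
complete search. Failed draws are dropped with a warning; more than 5% is a
hard error. The ensemble is summarised by per-yellowness-bin acrylamide
quantiles (`ensemble_envelope()`) and by the fraction of all ensemble front
points above the 50 µg/kg benchmark (`exceedance_fraction()`).

## The synthetic kinetic generator

Published rate constants for this network are external to the package, so
`generate_kinetic_set()` produces internally consistent stand-ins with the
statistical structure the analysis assumes. The relative rate structure is
drawn once from seeded log-uniform perturbations (factor 0.5–2) of a fixed
backbone in which Schiff-base formation/decay dominate and acrylamide
elimination is slow; every constant doubles per +20 °C (log-linear
transform, so the doubling holds exactly at all temperatures); each
parameter carries a 15% relative standard deviation for uncertainty draws.
Realism is then enforced by calibration: the whole set is scaled jointly by
bisection (in log scale, at most 100 iterations) until the simulated
acrylamide after 2 min at 200 °C lands between 1200 and 1300 µg/kg — the
reported severe-frying scale for this system. The joint scale is monotone
in final acrylamide far below substrate exhaustion, which this target is,
so the bisection is well posed.

What the generator does *not* emulate: the actual published values of
K1–K6, their true temperature sensitivities (the real network is
considerably steeper in temperature, which is why low-temperature
acrylamide from the generator sits higher than the published low-end front
values), or any correlation between constants. Consequently, tests passing
with synthetic kinetics validate the machinery — solvers, constraints,
equivalence detection, propagation — not the literature-specific figures:
the published acrylamide column of the operating-point table, the ~155 °C
compliance boundary, and the ~95% ensemble exceedance fraction are
reproducible only when a config file carrying the literature constants and
their confidence intervals is supplied.

## Numerical choices

* ODE solver: adaptive `lsoda` with rtol 1e-8, atol 1e-12. The tight
  absolute tolerance matters because front-relevant acrylamide
  concentrations sit near 1e-6 mmol/L, where a looser atol would cap
  relative accuracy well above the 1e-6 agreement the test suite demands
  against an independent fixed-step RK4 integrator (dt = 1e-4 min).
* Negative excursions: states below −1e-9 raise an error (model misuse);
  within [−1e-9, 0) they are clipped to zero on output (solver noise).
* Config round-trips: JSON and YAML serialise to ~15 significant digits;
  the schema validator rejects files with missing constants or fields.
* Determinism: every stochastic entry point (generator, GA, draws) takes an
  integer seed, uses it locally, and restores the global RNG state.

## Problem sizes in the test suite

The suite exercises the full pipeline at deliberately chosen scales: the
solver cross-validation runs NSGA-II at its default population 100 × 200
generations against a complete search with temperature step 0.25 °C; the
Monte-Carlo property checks use 50-draw ensembles solved by the coarse
complete search (level step 0.1–0.2, temperature step 2 °C); the
feasible-region interval check uses a 500 × 500 grid; oracle comparisons
use a 3 × 3 (t, T) grid and a 1500 × 1500 brute-force surrogate grid. These
sizes resolve every property being asserted while keeping the suite quick
to run; full-scale studies (1000 draws, default resolutions) use the same
code paths unchanged.

## Limitations

* Isothermal, uniform-temperature treatment of the slice; real fryers have
  internal gradients, so model times understate real times for the same
  chemistry.
* Single potato variety and composition; changing variety, thickness or
  pretreatment changes *b₀*, *X₀* and the initial sugar/asparagine pools.
* The 50 µg/kg benchmark is reported (via compliance flags), not imposed as
  a constraint on the optimization.
* The mmol/L → µg/kg conversion is an explicit assumption (see above).
* Equivalence uses an absolute 0.01 objective tolerance at all scales; at
  high acrylamide values this is far stricter in relative terms than at the
  low-acrylamide end where equivalent solutions actually occur.
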