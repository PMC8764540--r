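---
title: "Phase-resolved contextualization of PHA-cycle physiology"
author: "phaflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-resolved contextualization of PHA-cycle physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phaflux)
```

## The problem

*Pseudomonas putida* growing on octanoate under nitrogen limitation runs a
polyhydroxyalkanoate (PHA) cycle: the polymerase (PhaC) stores
(R)-3-hydroxyacyl-CoA as polymer while the depolymerase (PhaZ) releases
free (R)-3-hydroxyalkanoates (HA), which acyl-CoA synthetase (FadD)
reactivates at the cost of ATP. Engineering the PhaZ dose reshapes the
whole carbon economy of the cell: high-dosage strains stop accumulating
polymer, secrete monomers, divide more, and burn more carbon as CO2.

`phaflux` turns batch-culture physiology of such strains into
condition-specific constraint-based models and interrogates them three
ways: flux balance analysis (FBA) per growth phase, dynamic FBA (dFBA)
across the whole curve, and uniform Monte Carlo sampling of each phase's
flux polytope with median-flux comparisons between strains.

## Physiology to rates

Because stored polymer inflates both optical density and total cell dry
weight (CDW), all growth computations use **residual biomass** — total CDW
times $(1 - \mathrm{PHA}/100)$. The specific growth rate is the
least-squares slope of $\log_{10}$(residual biomass) versus time over a
phase window, multiplied by $\ln 10$ (2.303 to four digits). Windows
follow the phase convention, half-open $[t_0, t_1)$ with the terminal
phase closed, so a sample taken exactly at a boundary is attributed to the
following phase and a saturated boundary point cannot bias an exponential
fit.

All other measured quantities convert to specific rates
(mmol gCDW$^{-1}$ h$^{-1}$) by
$\Delta c / (M \cdot \Delta t \cdot \bar X)$, with $\bar X$ the arithmetic
mean of the residual biomass at the interval endpoints (a logarithmic-mean
strategy is available via `build_phase_rates(..., biomass_mean = "log")`).
Monomer masses default to the C8 species expected on octanoate feed — the
repeat unit at 142.20 g/mol (3-hydroxyoctanoate in chain) and the free
acid at 160.21 g/mol — and are overridable through `monomer_mass_table()`,
since the measurements themselves do not fix them.

Three phases partition the 24 h culture at 5 h and 10 h: early exponential
growth (I), late-exponential PHA/HA production (II) and stationary phase
(III). The boundaries are clock-defined, not substrate-defined, and
configurable.

The MicroResp CO2 assay is represented by its calibration hyperbola
$y = A x/(B + x)$ with the packaged coefficients $A = 1.73$, $B = -0.13$.
With $B < 0$ the curve is monotone *decreasing* in the OD570 reading on
its valid domain $x > 0.13$ and approaches $A$ from above; the package
asserts this direction for the packaged calibration and rejects readings
on the wrong side of the asymptote.

## Condition-specific models

Per strain and phase, four measured quantities clamp the base network:
octanoate exchange to $[-u(1+\tau), -u(1-\tau)]$ (negative flux is
uptake), the PHA sink, the HA exchange, and the biomass reaction each to
their measured rate $\pm\tau$. The default band $\tau = 0.05$ reflects
measurement noise; exact clamping ($\tau = 0$) is supported and forces
predictions to equal observations whenever feasible. The biomass
constraint is a two-sided band rather than a lower bound only: without the
upper bound, growth maximization overshoots wherever surplus carbon
exists, which breaks both the exact-clamping property and the growth-curve
reconstruction. Growth maximization remains the FBA objective in every
phase, including stationary phase where the band pins the optimum and the
sampler explores the residual space; no flux-distribution claim is ever
based on a single FBA vector, because optima are degenerate.

PHA accumulation is modelled as a sink draining the polymer repeat-unit
pool downstream of the polymerase, so percent-CDW storage is expressible
at steady state without a polymer term in the biomass reaction. The core
model's single biomass function is polymer-free; users loading other
models should check which biomass function they constrain.

Secretion of by-products other than HA is left at the base model's
defaults (the packaged core network has no such routes; for external
models a user can close them explicitly), matching supernatant assays in
which no other metabolites were detected.

## The core network

`core_pha_model()` builds a 52-reaction, 50-metabolite carbon- and
element-balanced network: octanoate activation (2 ATP equivalents via
AMP + PPi), beta-oxidation of the C8 backbone with the C6 and C4 rounds
lumped, both (R)-HA-CoA supply routes — the R-specific enoyl-CoA hydratase
(RECOAH3) and the 3-oxoacyl reductase route (RHACOAR80 with ECOAH3 and
HACD3i), which nets one NADH produced per NADPH consumed — the PHA
polymerase/depolymerase/reactivation cycle, TCA cycle with the canonical
reaction ids (CS, ACONTa/b, ICDHy, AKGDH, SUCOAS, SUCDi, FUM, MDH),
glyoxylate shunt (ICL, MALS), malic enzyme and pyruvate dehydrogenase as
the return route from C4 acids to acetyl-CoA, a gluconeogenic backbone
(PPCK, ENO, PGM, PGK, GAPD), lumped oxidative phosphorylation (P/O of 2
for NADH, 1 for FADH2), a non-growth ATP maintenance demand
(0.92 mmol gCDW$^{-1}$ h$^{-1}$ lower bound), and a precursor-based
biomass reaction draining 39 mmol C per gCDW
(`core_biomass_carbon()` = 0.468 gC/gCDW, declared next to the
stoichiometry so carbon audits and the synthetic generator use a
consistent value). Reduced cofactors carry their proton as a bookkeeping
convention, which lets `check_mass_balance()` verify every interior
reaction to machine precision without a free proton species. Without the
malic-enzyme/PDH return route the gluconeogenic backbone is a dead end and
glyoxylate-shunt flux is pinned exactly to biomass demand, degenerating
all cross-strain shunt comparisons; its inclusion is structural, not a
tuning choice.

The model is explicitly **not** a genome-scale reconstruction. Its role is
to make every pipeline stage testable offline; cross-strain flux
comparisons on it are direction-level only, and genome-scale magnitudes
(e.g. the published fold changes) are reachable only by loading the full
reconstruction through `load_model()`.

## Linear programming

Both `pracma::linprog` and `boot::simplex` fail on the degenerate
equality-constrained programs FBA produces (indexing bugs and singular
bases, observed directly), so the package carries a small bounded-variable
two-phase primal simplex (`lp_solve`). It recomputes the basic solution
from a fresh factorization at every pivot — on networks of this size that
costs microseconds and removes accumulated roundoff — and switches from
Dantzig pricing to Bland's rule after a run of degenerate pivots, which
guarantees termination. Feasibility and optimality tolerances are 1e-9;
all bounds must be finite (the packaged models use ±1000). On several
hundred random degenerate instances the solver agrees with an external
HiGHS implementation to 1e-6; inside the test suite its oracle is
brute-force vertex enumeration on small polytopes, to 1e-9.

## Dynamic FBA

`simulate_batch()` is static-optimization dFBA: at each step the active
phase's constraints are applied, the uptake bound additionally capped by
remaining substrate ($u \le \mathrm{oct}/(X\,\mathrm{d}t)$), and the FBA
fluxes advance the extracellular state. Two integrator choices matter:

* Biomass advances by the exact within-step exponential
  $X \leftarrow X e^{\mu \mathrm{d}t}$, and concentration updates use the
  exact integral of $X$ over the step. A constant-$\mu$ culture therefore
  reproduces $X_0 e^{\mu t}$ to machine precision, and the carbon audit
  closes to rounding error; plain forward Euler would carry a
  $\mu^2 t\,\mathrm{d}t/2$ relative error (about 0.2% over one phase at
  $\mathrm{d}t = 0.01$ h).
* The growth clamp uses the phase's *endpoint-integrated* rate
  $\ln(X_{t_1}/X_{t_0})/\Delta t$ rather than the regression rate. The
  regression rate describes the instantaneous exponential kinetics (and
  parameterizes the steady-state condition models), but piecewise
  exponential growth at that rate does not interpolate the measured curve
  when growth saturates inside a phase; the integrated rate does, by
  construction.

`simulate_batch()` defaults to `tolerance = 0` (exact tracking): the
reconstruction should follow the measurements, while the ±5% band belongs
to the steady-state models. On substrate exhaustion the production and
growth floors, then the maintenance demand, are relaxed toward zero,
giving a quiescent starved end-game instead of an error; the step index is
reported if even that fails. Default step 0.01 h; within a phase the LP is
re-solved only when the effective bounds change, so a full 24 h
trajectory costs a handful of LP solves until the substrate cap engages.

The reconstruction leaves ~0.7 mM of the 15 mM octanoate feed unconsumed
at 24 h for the wild type (≈5%): the generator's bookkeeping spends
phase-I carbon against the arithmetic-mean biomass while the simulated
culture integrates an exponential, whose time-average is smaller. This is
an inherent, documented discrepancy of endpoint-mean rate conversion, not
a carbon leak — the audit closes to 1e-12.

## Flux sampling

`achr_sample()` implements artificial-centering hit-and-run: directions
are differences between stored points and the running center (hence
automatically inside the null space of $S$), the feasible chord comes from
the bound box, and the next point is uniform on the chord. Warmup points
are LP optima of ± coordinate objectives plus seeded random ±1
objectives. The state is re-projected onto $Sv = 0$ every 997 steps to
scrub roundoff; every emitted point satisfies $Sv = 0$ within 1e-6 and
bounds within 1e-8, asserted en masse by `assert_samples_feasible()`.
Defaults are 5,000 kept points with thinning 100; the test suite and the
acceptance script use 2,000 × 20 per condition model, which reproduces
uniform-polytope oracles within Monte Carlo error at desk scale. Chains
are bit-reproducible for a fixed seed, and seeds are function arguments
that never leak into the caller's RNG state.

The mixing diagnostic is the **mixed fraction**: pair the i-th point of
the first half-chain with the i-th point of the second half and count the
fraction of pairs on opposite sides of the reaction's overall sample
median, averaged over non-constant reactions (constant reactions carry no
mixing information; an all-constant set returns an explicit NA signal).
0.5 indicates independent halves. The exact formula used by other
toolboxes is not published, so this definition is stated and tested
against its own enumeration oracle rather than assumed identical.

Median fluxes summarize each polytope ("most probable flux value"), and
`compare_strains()` forms mutant/wild-type ratios of signed median net
fluxes, classified as increased (> 1.2), reduced (< 1/1.2) or unaffected;
the thresholds are symmetric on the log scale and configurable, the
reference-zero case is classified `undefined` below a floor of 1e-6.
Summary reports are deliberately small named functions:
`atp_production_summary()` (sum of positive median ATP contributions,
maintenance excluded), `respiration_summary()` (|O2 exchange median|) and
`co2_production_summary()` (CO2 exchange median).

## What the synthetic generator emulates

`builtin_archetypes()` encodes the published 24 h endpoints per strain
(total CDW, %CDW PHA, free HA, viable cells, growth rate on residual
biomass, 15 mM octanoate feed, 0.085 g/L inoculum). The deterministic
trajectory grows residual biomass exponentially at the archetype rate
until the endpoint residual value, accumulates PHA and HA piecewise
linearly within phases according to per-phase weights, and declines
octanoate as cumulative product carbon plus an explicit CO2 channel — the
closure remainder, since the feed is exhausted in every strain — released
according to per-phase CO2 weights. Accumulator strains (KT2440, KT40Z,
M1) build most polymer in late exponential phase (weights 0.10/0.65/0.25)
with respiration tracking growth (0.50/0.35/0.15); hydrolyzer strains
(M2–M4, and the cluster deletion) secrete monomers into stationary phase
(0.10/0.55/0.35) with sustained respiration (0.30/0.30/0.40). These
weights are set once from the study's narrative (growth in phase I,
production in phase II, continued turnover and — for hydrolyzers — an
active stationary metabolism); with them, the derived wild-type phase-II
octanoate uptake is ≈3.9 and the high-dosage strain's ≈1.9
mmol gCDW$^{-1}$ h$^{-1}$, bracketing the published 3.8 vs 2.2 contrast
without being fitted to it.

Measurement noise is multiplicative lognormal per observation with CV 5%,
and each recorded value is the mean of three replicates, mirroring the
triplicate design behind the published error bands. The default sampling
grid (hourly through the exponential phase with an end-of-exponential
sample at 4.5 h, sparser afterwards) was chosen by a design-time power
analysis: it puts the phase-I regression's standard error near
0.007 h$^{-1}$, so the ±0.02 h$^{-1}$ recovery band is a ≈2.7σ statement.

What the generator does **not** emulate: sampling-time irregularities and
missing values, autocorrelated (instrument-drift) noise, diauxie or lag
phases, biological replicate-to-replicate variation beyond i.i.d.
measurement noise, and any regulatory dynamics. Passing tests therefore
demonstrate the pipeline's correctness on curves with the published
endpoint structure, not robustness to every pathology of real data. The
viable-cell and od570 channels are generated for schema completeness
(od570 only at the 24 h endpoint, inverted through the calibration from
the archetype's CO2 fold) and consumed by no flux computation.

## Numerical choices and degenerate inputs

* Solver tolerances: LP 1e-9; FBA solutions checked to $|Sv| <$ 1e-8;
  sampler feasibility 1e-6/1e-8; mass balance 1e-9.
* Zero measured rates clamp reactions to [0, 0]; a constraint that would
  reverse an irreversible base reaction is rejected.
* Growth-rate fits exclude non-positive residual biomass with a warning
  rather than erroring; negative production estimates from noise are
  clamped to zero.
* Ties/degeneracy in the LP are resolved deterministically (Bland's rule
  after 40 degenerate pivots), so every result is reproducible.
* `relative_co2` and `validate_phase` treat observed zeros explicitly
  (error, and 0-vs-0 → zero error, respectively).

## Desk-scale problem sizes

The shipped configuration keeps every stage interactive on one CPU: the
test suite samples 2,000 points (thinning 20) per condition model, the
acceptance script runs four condition models, a 100-seed recovery study
and two full dFBA reconstructions in well under a minute, and a
2-strain × 3-phase pipeline run at the 5,000 × 100 sampler default
completes in a few minutes. These sizes are the package's choices for a
meaningful mixed-fraction diagnostic at interactive speed, and all are
configurable upward.

## Known limitations

* The core network cannot reproduce genome-scale magnitudes: with
  near-identical wild-type and deletion-strain endpoint physiology, the
  phase-I TCA median ratio is ≈1.05–1.07 (direction only), against
  1.8–2.2 on the full reconstruction with its richer per-phase data.
* Phase boundaries are clock-based; a substrate-triggered phase switch is
  out of scope.
* The PHA sink is irreversible: stored polymer cannot be remobilized as a
  carbon source inside a later steady-state model, so starvation after
  feed exhaustion is quiescent rather than PHA-fuelled.
* Uptake kinetics are capacity caps, not Michaelis–Menten saturation.
* SBML reading is best-effort (Level 3 + fbc bounds/objective); the JSON
  dialect is canonical.
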