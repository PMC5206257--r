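---
title: "Methods: hybrid AA/CG solvation free energies and log D"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid AA/CG solvation free energies and log D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elbasolv)
```

This vignette is the package's account of its model, its numerical
choices, and what its tests do and do not demonstrate.

## The model

The package estimates distribution coefficients between water and
cyclohexane from solvation free energies,

$$\log D \approx \log P =
  \frac{\Delta G_\mathrm{solv}(\mathrm{water}) -
        \Delta G_\mathrm{solv}(\mathrm{cyclohexane})}{2.3\,R\,T},$$

with $R = 8.314$ J mol$^{-1}$ K$^{-1}$ and $T = 298$ K.  The factor 2.3 is
used literally (not $\ln 10 = 2.3026$); the difference is far below the
rounding of any tabulated free energy and is absorbed by the 0.02
tolerance applied when per-compound log D values are re-derived from
rounded ΔG columns.  Approximating log D by log P means one neutral
tautomer per compound: ionization and tautomer corrections are out of
scope, as is any automated force-field parameterisation — atomistic
parameters are consumed, never generated.

The system is a hybrid: the solute is all-atom, the solvent is
coarse-grained.  CG water is a Stockmayer fluid — each molecule one
Lennard-Jones site carrying an ideal point dipole.  CG cyclohexane is
three bonded, uncharged Lennard-Jones beads with σ = 4.1 Å and
ε = 3.19 kJ/mol; these are the non-polar lipid-tail bead parameters
scaled by the conventional 0.9 ring factor, and the package stores the
scaled values directly rather than re-deriving them at run time.  The
three beads form a closed ring of three harmonic bonds (r₀ = 4.05 Å,
k = 12.69 kJ/mol/Å²).  A two-bond chain would also satisfy a literal
reading of "three connected sites"; the ring was chosen because the beads
sit on alternating carbons of a closed ring and a triangle preserves that
symmetry.  The bond convention is $E = k (r - r_0)^2$, *without* the ½
prefactor, matching the force-constant value as shipped in simulator
input decks; with the ½ convention the same number would imply a bond
twice as stiff.

The water bead's σ, ε and dipole moment are not restated by the study
this package accompanies; the defaults (`elba_water_spec()`: σ = 3.05 Å,
ε = 2.30 kJ/mol, μ = 2.6 D) are taken from the published Elba water
model, and the rotational inertia (2.0 g/mol Å², water-like) is a
configuration choice of this package.  All four are plain arguments, and
the shipped YAML force-field files label them accordingly.

## Interactions: shifted-force everywhere

Every non-bonded interaction is truncated at $r_c$ = 12 Å with a
shifted-force construction, so that the energy *and the full vector
force* vanish continuously at the cutoff.  The exact functional forms of
the original Elba kernels are not reprinted in the accompanying study, so
the package adopts the standard construction and documents it as its own
realization: each radial kernel $r^{-n}$ of the multipole expansion is
replaced by

$$S_n(r) = \frac{1}{r^n} - \frac{1}{r_c^n} + \frac{n\,(r - r_c)}{r_c^{\,n+1}},$$

which has $S_n(r_c) = S_n'(r_c) = 0$.  Dipole–dipole interactions use
$S_3$ and $S_5$ on the two angular invariants, charge–dipole uses $S_3$,
charge–charge uses $S_1$, and the Lennard-Jones potential is shifted as
$U(r) - U(r_c) - (r - r_c)U'(r_c)$ — the same treatment for CG and atom
pairs.  Because the shift applies to every kernel, forces are exact
negative gradients (verified against central finite differences to
10⁻⁶ kJ/mol/Å in the tests) and torques satisfy
$\tau = \mu \times E$ with $E = -\partial U/\partial\mu$.  Atom–atom
electrostatics use the same shifted-force Coulomb instead of a mesh-Ewald
reciprocal sum.  For the neutral, desk-scale systems this package
targets, the neglected long-range tail is a documented model deviation,
not an approximation error the tests could hide: the shifted-force model
*is* the potential being simulated.

Cross-species Lennard-Jones parameters use Lorentz–Berthelot combination
(arithmetic σ, geometric ε), the convention of the atomistic force fields
whose parameters the package consumes.  Non-bonded interactions between
sites of the same molecule are excluded; for the small CG solvent
molecules and toy solutes shipped here the intramolecular physics is
carried entirely by bonds and constraints.

## Dynamics

The integrator is an impulse (r-RESPA style) multiple-timestep scheme:
CG–CG non-bonded forces and torques kick at the outer timestep
(6 fs = 2 fs × 3 by default) while all other forces — solute–solvent,
atom–atom, bonded — integrate on the inner 2 fs step.  The inner step is
a BAOAB Langevin splitting; with the thermostat off and `mts_ratio = 1`
it reduces exactly to velocity-Verlet (asserted in the tests against an
independently coded Verlet loop).  Solute and solvent are coupled to two
independent Langevin baths with friction γ = 1/τ, τ = 6 ps.  Rotational
degrees of freedom of the dipolar beads are propagated as linear rotors —
angular velocity always perpendicular to the dipole axis, free precession
between torque impulses — and are thermostatted with the same γ; whether
the original implementation used the same rotational coupling constant is
not documented, and one shared τ is the minimal assumption.

Two accuracy contracts pin the integrator down.  First, with all coupling
off, the total energy of a 100-bead CG water box drifts by less than
0.02 kJ/mol per bead over 10 ps, measured from a thermalized state (an
unequilibrated start conflates relaxation with integration error).
Second, 500 ps thermostatted runs hold the mean kinetic temperature
within 1 % of 298 K.  The reported kinetic temperature averages on-step
and mid-step (between-kicks) kinetic energies; on-step velocities alone
underestimate the temperature at a 6 fs impulse interval by ~1 % (the
standard Verlet on-step bias), and the half-step average cancels the
leading term, as leapfrog MD codes do.  The energy columns of the
observable series remain pure on-step quantities so that energy-drift
accounting stays consistent.

Pressure is regulated by a weak-coupling (Berendsen) barostat,
$\mu = [1 - (\delta t/\tau_p)\,\kappa\,(P_0 - P)]^{1/3}$ with τ_p = 6 ps
and a water-like default compressibility κ = 4.5 × 10⁻⁵ atm⁻¹, applied
once per outer step.  Scaling moves molecule centers and preserves
internal geometry.  The instantaneous pressure comes from the atomic
virial of all pair forces.  A guard aborts if the barostat would shrink
the box below twice the cutoff, where minimum-image evaluation would
silently break.  SHAKE enforces distance constraints after each position
half-step (tolerance $|d^2 - d_0^2| < 10^{-8}$ Å², corrections along
pre-step bond vectors, velocities corrected consistently).

All stochastic elements — initial velocities, thermostat noise, box
building — draw from R's RNG, so a seed makes whole trajectories
bit-reproducible, checkpoints restart exactly, and independent repeats
differ only through their seeds.

## Free energy protocol

Solute–solvent energy is scaled by the quartic coupling
$f(\lambda) = (1-\lambda)^4$: fully interacting at λ = 0, ideal-gas
solute at λ = 1.  The quartic power is the endpoint-smoothing device —
there is no soft-core modification and no split electrostatic/steric
legs, because the scaling applies to the *total* solute–solvent energy.
Intramolecular solute terms are never scaled: the decoupled solute must
behave as a gas-phase molecule, so its internal energetics stay on.

The λ grid is 25 equally spaced values from 0 to 0.96 (spacing 0.04).
Each repeat is one trajectory that visits the grid step-wise; within each
window the first quarter is discarded as equilibration and the unscaled
solute–solvent energy $U_{sv}$ is sampled, giving
$\partial U/\partial\lambda = f'(\lambda)\,U_{sv}$.  Window means are
integrated with the composite trapezium rule after linearly extrapolating
the last two grid points (0.92, 0.96) to λ = 1; the reference protocol
simulates 4.8 ns per window with 1.2 ns discarded and 0.6 ps sampling,
which is cluster-scale work.  The shipped `ti_preset("desk")` keeps the
grid and the discard fraction but shrinks windows to 10 ps with 0.06 ps
sampling, so the full workflow runs in about a minute per repeat on one
CPU for a 125-bead box.  Repeats are combined as mean ± sd/√n.
ΔG_solv is minus the decoupling integral.

Two independent checks guard the machinery: a null-coupled solute (all
interactions zero) yields exactly 0 ± 0, and an exponential-averaging
(free-energy-perturbation) estimator evaluated on the *same* trajectories
must agree with TI within combined statistical error.  FEP is an internal
oracle only; it is deliberately not offered as an alternative production
estimator.

## Analysis layer

`summary_metrics()` reports MAD, MSD (= mean(pred − exp)), RMSD and
Pearson's R; zero variance on either side makes R an explicit error
state, never a silent 1.  Sign accuracy counts sign(pred) = sign(exp),
with an exact zero on one side only counting as a mismatch (both zero
match).  The significance-filtered variant drops records where either the
prediction or the experiment is not significantly different from zero at
95 % confidence, testing $|x|/\mathrm{se}$ against a normal quantile.
The default is the one-sided critical value (1.645); the two-sided
variant (1.96) is available via `alternative =`.  Both are defensible
readings of "significantly different from zero at 95 %", and on the
packaged table they differ by two retained compounds (45 vs 44) and two
percentage points — a useful illustration of how sensitive such filtered
summaries are to the test convention.

BEDROC follows the Truchon–Bailey formulation: compounds ranked
worst-first by absolute deviation, members' ranks summed with weights
$e^{-\alpha r/N}$ and normalised to [0, 1].  α defaults to 20, the
conventional early-recognition setting; since the value used for the
published group tables is not recorded, α is a mandatory, logged
parameter of every report rather than a hidden constant.  Ties in scores
break by first occurrence in input order.  The uniform baseline is a
seeded Monte-Carlo average over random member placements (checked against
exhaustive enumeration at n = 5, N = 10 in the tests), uncertainty comes
from 500 bootstrap resamples, and the per-group t-test compares a group's
absolute deviations with the entire population (group included) using
pooled variance — the closest literal reading of "compared to the entire
population" — with a Welch variant available.

The packaged `table1.csv` transcribes the 53-compound results table
(per-phase ΔG ± SE, predicted and experimental log D).  Chemical-group
*memberships* are not part of that table — they came from a structural
perception program — so the group machinery is exercised on synthetic
memberships with planted enrichment, and `groups_stub.csv` documents the
input format for users who bring their own group assignments.

## What the synthetic fixtures do and do not show

The toy systems (single LJ site, charged site, constrained diatomic;
27–216-bead solvent boxes at roughly a quarter of liquid water's number
density, so that a 24 Å minimum-image box stays affordable) exercise
every code path: all pair-interaction kinds, SHAKE, both thermostat
groups, the λ machinery.  Passing tests demonstrate correctness of the
mechanics — conservation laws, estimator agreement, reproducibility — not
fidelity to experimental solvation physics: a desk-scale toy box has no
claim to reproducing liquid-state structure, and the package makes none.
Reproducing tabulated per-compound free energies would require the
cluster-scale protocol and the original compound topologies, which is
exactly why the packaged results table, not fresh simulation, feeds the
analysis-layer reproduction.

## Numerical choices and limitations

* Internal units: Å, fs, g/mol, K, atm, kJ/mol, e; Coulomb prefactor
  1389.35458 kJ Å mol⁻¹ e⁻².  `elba_constants()` exposes the conversion
  layer.
* Minimization is adaptive steepest descent (step × 1.2 on acceptance,
  halved on rejection, capped at 1 Å), with small dipole rotations along
  torque directions; it targets relaxation before dynamics, not deep
  optimization.
* The λ = 1 endpoint is always extrapolated, never simulated; with
  f′(0.96) = −2.56 × 10⁻⁴ the integrand is already ~0 there, so the
  extrapolation choice (last two points vs a longer fit) is numerically
  inert for well-behaved integrands.
* The cell list requires at least 3 cells per dimension and falls back to
  the brute-force double loop otherwise; both paths are compared to
  10⁻⁸ relative in the tests.
* Orthorhombic periodic boxes only; no long-range dispersion corrections;
  no replica exchange; harmonic bonds are the only bonded terms shipped
  (angles/dihedrals would enter the same inner-force slot if supplied).
* The 3.6 ns-vs-4.8 ns convergence bookkeeping is exposed as
  `convergence_delta()`, which flags compounds whose estimate moves by
  more than 1 kJ/mol between two sampling lengths.
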