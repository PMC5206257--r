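# elbasolv

Hybrid all-atom/coarse-grained solvation free energies and water/cyclohexane
distribution-coefficient (log D) prediction, as an R package.

## The scientific problem

Whether a small molecule prefers water or an apolar phase — its distribution
coefficient, log D — is a basic physicochemical property and a standard
benchmark for molecular force fields.  Computing it from first principles
means estimating the solvation free energy ΔG_solv in each phase and taking

    log D ≈ log P = (ΔG_solv(water) − ΔG_solv(cyclohexane)) / (2.3 R T)

with R = 8.314 J mol⁻¹ K⁻¹ and T = 298 K.  Doing this with all-atom solvent
is expensive; this package implements the *hybrid* alternative: the solute
keeps its all-atom (GAFF-style) representation while the solvent is
coarse-grained.  Water is a Stockmayer bead — a point dipole embedded in a
Lennard-Jones site — and cyclohexane is three bonded, uncharged
Lennard-Jones beads (σ = 4.1 Å, ε = 3.19 kJ/mol; bond r₀ = 4.05 Å,
k = 12.69 kJ/mol/Å² in the E = k(r−r₀)² convention).

All non-bonded interactions (LJ, charge–charge, charge–dipole,
dipole–dipole) are truncated at 12 Å with shifted-force kernels, so energy
and force go continuously to zero at the cutoff.  Atom–atom electrostatics
use the same shifted-force Coulomb treatment rather than a reciprocal-space
mesh sum — a deliberate desk-scale simplification for neutral solutes,
documented in the methods vignette.

The toolkit covers the full workflow:

* **forcefield** — Elba-style CG parameters, shifted-force pair potentials
  with analytic forces and torques, cell-list and brute-force system
  evaluation (`lj_shifted_force()`, `dipole_dipole_sf()`,
  `total_energy_forces()`);
* **system building** — coarse-graining of all-atom solvent configurations
  (water beads at the oxygen positions, cyclohexane beads on C1/C3/C5),
  box building, solvation, toy solutes (`map_water_to_cg()`, `build_box()`,
  `solvate()`, `make_toy_solute()`);
* **dynamics** — steepest-descent minimization, an impulse multiple-timestep
  integrator (CG–CG forces at 6 fs, everything else at 2 fs) with BAOAB
  Langevin thermostats (τ = 6 ps, separate solute/solvent baths, rotational
  degrees of freedom included), a weak-coupling barostat and SHAKE
  (`run_md()`, `step_mts()`, `shake()`);
* **free energy** — thermodynamic integration with fourth-power coupling
  f(λ) = (1−λ)⁴ over 25 λ values from 0 to 0.96, trapezium integration with
  linear extrapolation to λ = 1, independent repeats, and an
  exponential-averaging (FEP) cross-estimator (`run_solvation_fe()`,
  `ti_integrate()`, `fep_estimate()`);
* **analysis** — log D conversion with error propagation, MAD/MSD/RMSD/R,
  sign accuracy with a significance filter, and BEDROC chemical-group
  enrichment diagnostics with bootstrap uncertainties (`log_d()`,
  `summary_metrics()`, `bedroc()`, `group_report()`);
* **io/cli** — PDB/XYZ structure input, extended XYZ with dipole columns,
  CSV prediction tables, YAML force-field files, and an `elbasolv`
  command-line wrapper (`inst/scripts/elbasolv`).

A transcription of the 53-compound blind-challenge results table (per-phase
ΔG_solv ± SE, predicted and experimental log D) ships as
`inst/extdata/table1.csv` and drives the analysis layer end to end.

## A worked example

Solvate a toy Lennard-Jones solute in a small CG water box and estimate its
solvation free energy with the desk-scale TI preset (10 ps windows, the
same 25-point λ grid as the full protocol):

```r
library(elbasolv)

box <- build_box("water", 125, 25, seed = 1)
sol <- make_toy_solute("lj_site", center = c(12.5, 12.5, 12.5))
sys <- solvate(sol, box)
sys <- minimize_steepest_descent(sys, max_steps = 300)
est <- run_solvation_fe(sys, md_protocol(), ti_preset("desk"),
                        n_repeats = 2, seed = 1)
est
#> Delta G_solv (water) = -0.40 +/- 0.12 kJ/mol (2 repeats)
```

The weakly attractive toy solute (ε = 0.5 kJ/mol) is slightly stabilised by
the low-density toy water bath; the independent FEP estimator on the same
trajectories (`attr(est, "fep")`) agrees within the statistical error.

The packaged results table reproduces the published quality statistics:

```r
tab <- elba_table1()
m <- summary_metrics(tab$logd_pred, tab$logd_exp)
round(c(mad = m$mad, msd = m$msd, rmsd = m$rmsd, r = m$r), 2)
#>  mad  msd rmsd    r
#> 1.81 0.31 2.42 0.64
round(sign_accuracy(tab$logd_pred, tab$logd_exp))            # 77
round(as.numeric(sign_accuracy_filtered(tab)))               # 82
deviation_extremes(tab$logd_pred, tab$logd_exp, tab$compound_id)[c("max", "max_id")]
#> $max  8.1     $max_id  74
```

Or from a shell:

```sh
inst/scripts/elbasolv analyze --table inst/extdata/table1.csv --out stats.csv
```

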