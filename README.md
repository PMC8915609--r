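# ljrefit

Refitting Lennard-Jones force-field parameters against solvation free
energies and liquid densities — with a desk-scale simulation and free-energy
backend so the whole loop runs on one CPU with no external software.

## Who this is for

Fixed-charge force fields (GAFF-style) describe nonbonded interactions by
per-atom-type Lennard-Jones parameters (ε, σ) plus partial charges. When the
charge scheme changes — e.g. implicitly polarized charges built by averaging
vacuum and continuum-derived charge sets — the LJ parameters are no longer
self-consistent with the charges, and predictions of the solvation free
energy ΔG_solv (and hence of relative solubilities) degrade. This package
implements the refitting methodology for that situation: everything needed to
*optimize* LJ self-parameters and pair-specific water-interaction modifiers
against reference ΔG_solv and density data, for force-field developers and
computational chemists who want to study or reuse the fitting machinery
itself.

## What is inside

* **Force-field model** — atom types, modified Lorentz-Berthelot combining
  rules `ε_ij = (1+ξ)√(ε_i ε_j)`, `σ_ij = (1+ζ)(σ_i+σ_j)/2`, plain-text
  parameter files, GROMACS-style nonbonded export.
* **Charges** — implicitly polarized charge construction (vacuum/continuum
  averaging) and mole-fraction interpolation for binary mixtures.
* **Toy engine** — Metropolis Monte Carlo for rigid LJ/point-charge molecules
  in periodic boxes: NVT, NPT (densities with 5-block standard errors), Widom
  test-particle insertion.
* **Alchemy** — solvation free energies ΔG_solv = G(coupled) − G(decoupled)
  along a λ pathway with the 1-1-48 softcore (α = 0.003), MBAR estimation
  with overlap diagnostics and bootstrap errors, and λ-schedule
  redistribution toward equal per-interval uncertainties.
* **Objective and optimizer** — RMSD/MAE/slope/Pearson statistics, grouped
  RMSD tables, the weighted RMSD-ratio objective
  `Z = w_dG·RMSD_dG/RMSD_dG_ref + w_ρ·RMSD_ρ/RMSD_ρ_ref`, Nelder-Mead with
  oriented multi-start restarts, and a sequential atom-type adaptation
  scheduler (one type at a time, earlier results frozen).
* **Solubility** — relative solubilities `ln(c_A/c_B) = −β(ΔG_A − ΔG_B)` with
  uncertainty propagation and all-pairs enumeration.
* **Synthetic data** — a seeded toy library with known truth parameters so
  the full generate → fit → evaluate loop is testable end to end.
* **CLI** — `inst/cli/ljrefit.R` with commands
  `fit | evaluate | dgsolv | density | relsol | fixtures`.

## Worked example: recover known parameters from synthetic data

```r
library(ljrefit)

lib      <- build_toy_library(n_types = 2, seed = 7)   # truth parameters drawn here
settings <- toy_settings(seed = 123)
ref      <- synthesize_reference(lib, settings, noise_spec())  # "experimental" data
evaluator <- make_reference_evaluator(lib, ref, settings)

start <- perturb_truth(lib)        # epsilon +20 %, sigma +5 %, xi/zeta reset to 0
fit   <- sequential_fit(lib$schedule, evaluator, start,
                        n_restarts = 2, max_iter = 45)

fit$report[, c("type", "kind", "rmsd_dG_ref", "rmsd_dG", "Z")]
```

On this seed the four tasks (self and water-interaction for each of two
types) print:

```
  type              kind rmsd_dG_ref      rmsd_dG            Z
1   t1              self   0.6329590 0.0141143602 0.1237363666
2   t1 water-interaction   1.0270976 0.0014154130 0.0013780706
3   t2              self   0.5319101 0.0070865271 0.0380521801
4   t2 water-interaction   0.6903520 0.0004592729 0.0006652735
```

The objective Z starts at 2 per task (both RMSD ratios at their reference
values with unit weights) and drops to ≪ 1; the fitted parameters land on the
truth values to 0.4 % in ε and σ, and the water-interaction modifiers to
±0.002 (the whole run takes about two minutes on one CPU):

```
t1: eps err 0.31 %  sigma err 0.07 %
t2: eps err 0.18 %  sigma err 0.32 %
override t1-wO: truth (-0.048, -0.100)  fitted (-0.046, -0.101)
override t2-wO: truth ( 0.142, -0.012)  fitted ( 0.142, -0.011)
```

A single solvation free energy through the alchemical route:

```r
solv <- molecule_spec("solvent", site_spec("S"), mass = 40)
ps   <- parameter_set(list(atom_type("A", 0.6, 0.31), atom_type("S", 0.8, 0.34)))
sys  <- system_spec(list(list(molecule = solv, count = 80, role = "solvent"),
                         list(molecule = molecule_spec("probe", site_spec("A"),
                                                       mass = 30),
                              count = 1, role = "solute")),
                    box_edge = 1.9, temperature = 86.6)
fe <- solvation_free_energy(sys, ps, uniform_schedule(6),
                            sim_settings(temperature = 86.6, n_steps = 9000,
                                         equil_steps = 3000, seed = 17))
fe$dG           # kJ/mol, negative = favorable solvation
fe$per_interval # per-interval dG and uncertainties (they sum to fe$dG exactly)
```

## Layout

```
R/            forcefield, charges, systems, toysim, alchemy, mbar, objective,
              solubility, optimizer, scheduler, synthetic, cli
src/          Monte Carlo engine (Rcpp)
vignettes/    methods.Rmd — models, estimators, design decisions, limitations
tests/        testthat suite incl. test-acceptance.R
scripts/      acceptance.R
inst/cli/     command-line entry point
inst/extdata/ published benchmark summary statistics (plain-text CSV)
```
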