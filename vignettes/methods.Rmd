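---
title: "Methods: refitting Lennard-Jones parameters against solvation free energies and liquid densities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: refitting Lennard-Jones parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Fixed-charge force fields describe nonbonded interactions by per-atom-type
Lennard-Jones (LJ) parameters $(\varepsilon, \sigma)$ plus fixed partial
charges. When the charge scheme changes — for instance, when vacuum and
continuum-derived charges are averaged to represent polarization implicitly —
the self-consistency of the LJ parameters with the charges is disturbed, and
solvation free energies $\Delta G_\mathrm{solv}$ computed from the model
degrade. `ljrefit` implements the machinery to *refit* LJ parameters against
experimental solvation free energies and liquid densities: the parameter data
model, the objective function, the derivative-free optimizer, a sequential
atom-type adaptation scheduler, and — so the entire loop can be exercised
without external MD or quantum-chemistry software — a desk-scale Monte Carlo
engine with an alchemical free-energy backend and a synthetic-data generator
with known ground truth.

## Models and estimators

### Pair interactions

The LJ pair potential is
$u(r) = 4\varepsilon\left[(\sigma/r)^{12} - (\sigma/r)^{6}\right]$
with $\varepsilon$ in kJ/mol and $\sigma$ in nm (units are fixed package-wide:
kJ/mol, nm, e, K, bar; $R = 8.314462618\times10^{-3}$ kJ/(mol K)). Unlike
pairs combine by Lorentz–Berthelot rules. For interactions with water-model
oxygens the rules carry dimensionless adaptable modifiers $\xi_{ij}$ and
$\zeta_{ij}$:

$$\varepsilon_{ij} = (1+\xi_{ij})\sqrt{\varepsilon_i\varepsilon_j},\qquad
  \sigma_{ij} = (1+\zeta_{ij})\,\tfrac{1}{2}(\sigma_i+\sigma_j).$$

The *multiplicative* placement of the modifiers is a design choice of this
package: dimensionless modifiers that reduce exactly to plain
Lorentz–Berthelot at $\xi=\zeta=0$ are the only form in which "set to zero"
recovers the default rules without unit bookkeeping. The convention is
isolated in `combine_pair()`; an additive variant would be a one-line change
and every test of the surrounding machinery is form-independent. Water
hydrogen types carry $\varepsilon = 0$ and do not participate in LJ
interactions.

### Charges

Implicitly polarized charge sets are the per-site arithmetic mean of
vacuum-phase and continuum-solvent charges (`ipolq_mod_average()`). For a
binary mixture, the charges of compound A are interpolated linearly in its
mole fraction between the sets derived in the continuum of A and of B
(`mixture_charges()`). Linearity is again the only reading consistent with a
single mole-fraction weight; it preserves net charge exactly and is monotone
per site. Charge sets are file inputs — no quantum chemistry is performed.

### The toy simulation engine

The engine replaces production MD with Metropolis Monte Carlo of rigid
molecules (monatomic or small multi-site) in periodic cubic boxes: at desk
scale only equilibrium averages matter, so a sampler with exact detailed
balance — acceptance $\min(1, e^{-\beta\Delta W})$ — is preferable to
integrating dynamics. Specifics:

* minimum-image convention with a spherical cutoff (`r_cut` defaults to
  1.2 nm, clamped to `0.99 * box/2` in small boxes), LJ truncation with the
  standard analytic isotropic tail correction applied to energy and to the
  volume-move work term;
* electrostatics as truncated-and-shifted Coulomb, *not* Ewald summation —
  the default test systems are neutral LJ fluids, so the electrostatic
  approximation never drives an acceptance result; Ewald would be out of
  proportion for the fitting-logic test surface;
* NPT sampling via volume moves in $\ln V$ with the $(N_\mathrm{mol}+1)$
  Jacobian weight. The reported density is the production average of the
  *instantaneous* mass density $m/V$ with a 5-block standard error. (The
  alternative estimator $m/\langle V\rangle$ carries an exact $N/(N+1)$
  finite-size bias — 1% at $N=100$ — while $\langle m/V\rangle$ is exactly
  $pM/(RT)$ for an ideal gas; this is also what standard MD analysis tools
  average.)

The engine seeds R's RNG, so fixed settings give bit-identical trajectories.

### Alchemical solvation free energies

$\Delta G_\mathrm{solv}$ is computed along a pathway of $K$ states in which
only solute–solvent interactions are scaled by $\lambda\in[0,1]$ ($\lambda=0$
decoupled, $\lambda=1$ coupled). The LJ part uses the 1-1-48 softcore

$$u_\mathrm{sc}(r;\lambda) = \lambda\, u\!\left(r_\mathrm{sc}\right),\qquad
  r_\mathrm{sc} = \left(\alpha\sigma^{48}(1-\lambda) + r^{48}\right)^{1/48},$$

with $\alpha = 0.003$: finite at $r=0$ for $\lambda<1$, identically zero at
$\lambda=0$, and *exactly* the LJ potential at $\lambda=1$ (the code
special-cases the endpoint so the identity is bitwise). The high distance
power makes the softcore a very sharp switch, so the invariant suite pins the
properties (endpoints, finiteness, $\lambda$-continuity) rather than one
algebraic form. Solute charges, when present, scale linearly in $\lambda$;
the default toy solutes are neutral, a documented limitation.

Each state is sampled by an independent equilibrated NVT run; every recorded
configuration is evaluated at all $K$ states, giving the reduced potential
matrix $u_{kn} = \beta U^{(k)}_n$ (only the solute-solvent term enters; the
solvent-solvent energy is common to all states and cancels). Free energies
come from the MBAR estimator: self-consistent iteration with an adaptive
Newton switch on the log-sum-exp form, tolerance $10^{-10}$ on the reduced
free energies, asymptotic covariance for uncertainties, and the state-overlap
matrix as a diagnostic (a warning fires when the smallest consecutive overlap
drops below 0.03). Bootstrap uncertainties resample configurations within
each state. The $\lambda$ schedule is adjusted in (default) 3 trial rounds by
inverting the piecewise-linear cumulative per-interval uncertainty profile so
predicted per-interval uncertainties equalize — a simplified, deterministic
variant of adaptive $\lambda$-placement; already-equal profiles are a fixed
point. Alchemical runs are NVT at the stated box, so the result is strictly a
Helmholtz quantity; at these densities and system sizes the $p\Delta V$ term
is far below the statistical resolution.

As an independent route, `widom_mu_excess()` estimates the excess chemical
potential by test-particle insertion into stored pure-solvent configurations,
$\mu_\mathrm{ex} = -RT\ln\langle e^{-\beta\Delta U}\rangle$. The two routes
are never collapsed: the acceptance suite requires them to agree within
3 times the combined uncertainty at moderate solvent density (Widom insertion
degrades systematically in dense fluids; that regime is deliberately avoided
for the cross-check).

### Objective, optimizer, scheduler

The refitting objective for one optimization step is the weighted sum of
RMSD ratios

$$Z = w_{\Delta G}\,\frac{\mathrm{RMSD}_{\Delta G}}{\mathrm{RMSD}_{\Delta G}^\mathrm{ref}}
    + w_{\rho}\,\frac{\mathrm{RMSD}_{\rho}}{\mathrm{RMSD}_{\rho}^\mathrm{ref}},$$

where the "ref" normalizers are recomputed with the *current* (unaltered)
parameter set before each task, so both properties enter dimensionlessly and
$Z=2$ at unit weights marks the no-improvement baseline. The weighted *sum*
(rather than product or maximum) is the form in which the weights act
linearly and independently per property. Weights default to 1 and 1 — both
properties matter equally unless a task says otherwise; the published
workflow defines them per step but does not print values.

Minimization uses a hand-rolled Nelder–Mead downhill simplex (coefficients
1, 2, 0.5, 0.5 — the standard choice) because the objective is noisy:
simulation noise defeats difference-quotient derivatives, while simplex
ranking only needs function comparisons. Bounds are enforced by projection
onto the box (defaults: $\pm50\%$ of the initial $\varepsilon$, $\pm20\%$ of
$\sigma$, $\xi,\zeta\in[-0.5,0.5]$); self-task coordinates are scaled by
their initial values so $\varepsilon$ and $\sigma$ are commensurate.
Restarts with differently oriented initial simplices (sign patterns of the
offsets, 4 by default) guard against local minima; the best restart wins.
Convergence: relative f-spread below `tol` *and* simplex diameter below
`diam_tol`; hitting `max_iter` flags the result unconverged rather than
erroring.

Atom types are adapted *sequentially*: each task optimizes one type's two
coefficients (self $\varepsilon,\sigma$ or water-interaction $\xi,\zeta$)
while everything previously fitted stays frozen, and the schedule validator
rejects any task whose data subset involves a type that is neither fixed nor
already optimized — compound complexity can only grow along the schedule.
`default_adaptation_order()` records the canonical 21-type order (ring sp3
carbon first).

## The synthetic world

`build_toy_library()` generates a miniature analogue of a refitting campaign
with known ground truth. Its defaults are the stated world of the acceptance
tests:

* adaptable types with truth parameters drawn once per seed from
  $\varepsilon^*\in[0.2, 1.2]$ kJ/mol, $\sigma^*\in[0.25, 0.45]$ nm, and
  water-interaction modifiers $\xi^*,\zeta^*\in[-0.15, 0.15]$;
* two fixed solvent types: a neutral reference solvent (for self tasks) and
  a designated water-like oxygen `wO` (for $\xi/\zeta$ tasks), plus an inert
  `hw` hydrogen with $\varepsilon=0$;
* per type: pure-liquid density systems (50 molecules) at three temperatures
  and solvation systems (80 solvent molecules) at two solvent densities —
  solvation sizes sit inside the 60–150-particle window that keeps a full
  recovery run in the minutes range; a rigid homonuclear dimer of the last
  type adds multi-site coverage;
* state points are chosen in *reduced* units ($T^* = RT/\varepsilon^*$
  between 0.68 and 0.76 for the pure liquids, initial $\rho^*=0.8$) so each
  species sits in its stable liquid range at 1 bar — the toy species are
  noble-gas-like, with molar masses in $[30, 120]$ g/mol, so absolute
  temperatures are low (tens of K) while all reduced quantities are
  liquid-typical;
* measurement noise is homoscedastic Gaussian per property (no experimental
  error model is published; homoscedastic is the minimal assumption).

Reference "experimental" values are produced by running the engine at truth
parameters with per-system seeds. The reference evaluator used by
`sequential_fit()` reruns the same pipeline with the *same seeds* at trial
parameters (common random numbers), so with zero noise the objective is
exactly zero at truth and the fit is a pure test of the optimizer and
plumbing. Two estimator choices keep the loop fast and the objective smooth:
densities are rerun NPT (parameters of the liquid itself change), while
solvation free energies use Widom insertion into solvent configurations that
are sampled *once* — solvent types are never fitted, so the stored
configurations are independent of the trial parameters and the
$\Delta G$ part of the objective is a smooth deterministic function of them.
The full alchemical route remains first-class and is cross-checked against
Widom in the acceptance suite; it is not used inside the recovery loop
purely for cost reasons.

What a green recovery test establishes: the objective, optimizer, scheduler
and estimators interlock correctly, and the two-coefficient tasks are
identifiable from three densities plus two solvation free energies. What it
does *not* establish: transferability to real chemistry — multi-site charged
molecules, real water models, experimental data with structured errors, or
the published system scale (hundreds of systems, GROMACS-scale MD).

## Numerical choices

* MBAR: tolerance $10^{-10}$ on reduced free energies; the covariance uses
  the K-dimensional eigendecomposition reduction with a pseudo-inverse
  fallback for the (structurally) singular inner matrix.
* Engine runs in the toy pipeline default to 2000 sweeps (700 equilibration)
  for densities — about 1% density noise, well below the 2% $\sigma$
  recovery tolerance through the $\rho\propto\sigma^{-3}$ lever arm — and
  are deliberately short; all lengths are config-exposed.
* Nelder-Mead per task: 2 restarts, 45 evaluations each in the packaged
  recovery runs (a scaled-down budget chosen for the minutes-range runtime;
  the optimizer itself defaults to 4 restarts).
* Temperature bins for grouped reporting are lower-exclusive /
  upper-inclusive, so a boundary temperature belongs to the lower bin.
* Regression slopes are least-squares through the origin (a single slope
  near 1 with no intercept is what the evaluation reports); Pearson R is the
  ordinary centered correlation.
* Degenerate inputs error early and explicitly: empty datasets, zero
  variance in regression, non-positive reference RMSDs, cutoffs exceeding
  half the box.

## Known limitations

* No Ewald electrostatics and no charge decoupling in the alchemical path;
  charged solutes would need both.
* Widom insertion degrades in dense fluids; the recovery loop's $\Delta G$
  observables inherit whatever insertion bias exists, which is exactly
  cancelled between reference and refit by common random numbers but would
  not cancel against real data.
* Rigid molecules only; no bonded-parameter fitting.
* The NPT density estimator assumes the volume-move work term includes the
  tail-correction change; runs with `tail_correction = FALSE` at state
  points near coexistence will show small cutoff-dependent shifts.
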