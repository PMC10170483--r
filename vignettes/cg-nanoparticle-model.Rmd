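---
title: "Coarse-grained modelling of monolayer-protected gold nanoparticles with cgnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained modelling of monolayer-protected gold nanoparticles with cgnp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgnp)
```

## The model

`cgnp` implements a coarse-grained (CG) model of self-assembled-monolayer
gold nanoparticles (SAM-AuNPs): a metal core of 144 gold beads whose 60
sulfur grafting points are promoted to *core-decoy* (CD) beads, each
carrying one thiol ligand — octanethiol (OT, hydrophobic) or
11-mercaptoundecanoic acid (MUA, terminally charged). The core (Au + CD)
moves as a single rigid body. Two design rules concentrate all of the
core's energetics into the CD shell:

* every Lennard-Jones interaction involving Au, and the CD–CD
  interaction, is purely repulsive (`epsilon = 1e-4` kJ/mol);
* the CD cross terms against the shell, water and ion beads are the
  *fitted* parameters of the model (the pair table shipped in
  `inst/extdata/cgnp_default.ff`).

This makes the internal arrangement of the gold interior energetically
irrelevant: only the CD shell radius and count matter. The default core
generator therefore uses a deterministic spherical-Fibonacci layout (60
CDs on a 1.0 nm shell, gold filling concentric inner shells at a compact
pitch) and accepts externally supplied coordinates when a specific
structure is required.

### Functional forms and units

Nonbonded interactions are Lennard-Jones with two normalised forms:

* 9-6 between ordinary beads, `U = (27/4) eps ((s/r)^9 - (s/r)^6)`, with
  its minimum `-eps` at `r = (3/2)^(1/3) s`;
* 12-4 for any pair involving the water bead `W`,
  `U = (3 sqrt(3)/2) eps ((s/r)^12 - (s/r)^4)`, minimum `-eps` at
  `r = 3^(1/8) s`.

Bonded terms are harmonic without the 1/2 prefactor —
`U = k_b (b - b_eq)^2` and `U = k_theta (theta - theta_eq)^2` — matching
the LAMMPS `harmonic` convention, so a Boltzmann-distributed bond has
variance `kB T / (2 k_b)`. The same no-half convention applies to the
centre-of-mass umbrella restraint (a `1/2` variant is available via
`engine_config(restraint_half = TRUE)`).

Internally everything is nm / kJ/mol / amu / ps (a consistent unit
system: 1 kJ/mol = 1 amu nm²/ps²). Parameter files keep the
printed-table units (sigma and bond lengths in Å); they are converted on
load, and LAMMPS data/dump files are written/read in Å.

### Provisional parameters

Only the fitted CD cross terms, the repulsive-core rules and the
similarity substitutions (CD:ASP from CD:CT2; CD:SOD and CD:CLA from
CD:W) are pinned values of this model. The *diagonal* parameters of the
shell/solvent/ion beads and the bonded tables shipped in the default
force field are reference or provisional values supplied so that the
engine fixtures and tutorials are self-contained; users targeting
published CG force-field compatibility should substitute the official
tabulated values (`read_forcefield()` accepts any file in the documented
grammar). Bead masses are standard atomic/group masses with the water
bead representing three molecules (54.05 amu).

## The engine

The engine is a desk-scale velocity-Verlet integrator with:

* Langevin (Ornstein–Uhlenbeck) thermostatting — `friction = 0` gives
  symplectic NVE;
* rigid-body propagation of the cores: quaternion orientation, constant
  body-frame inertia tensor, torque-driven angular momentum updates.
  Internal core distances are preserved exactly (positions are always
  reconstructed from the quaternion), and intra-core pair interactions
  are excluded;
* Verlet-listed nonbonded forces, plain truncation at the cutoff
  (default 1.5 nm), 1-2 and 1-3 bonded exclusions;
* damped shifted-force (DSF) Coulomb within the cutoff for the charged
  beads (ASP/SOD/CLA), scaled by a relative permittivity (default 80,
  since the CG water bead carries no charge and screening must enter
  through a constant);
* a centre-of-mass distance restraint `U = k (|r_ab| - r0)^2`
  distributed mass-weighted over the group members, with optional
  constant-velocity motion of `r0` (pulling).

Two numerical choices deserve a note. First, plain truncation makes the
*recorded* total energy jump whenever a pair crosses the cutoff, which
is a bookkeeping artifact rather than integrator error; for strict
conservation measurements `engine_config(lj_shift = TRUE)` subtracts the
pair energy at the cutoff (the LAMMPS `shift yes` analogue, forces
unchanged). Second, the Langevin step is applied as an exact
Ornstein–Uhlenbeck update after the Verlet step; for rigid bodies the
same update acts on the centre-of-mass velocity and on the angular
momentum with body-frame noise covariance proportional to the inertia
tensor, so equipartition holds over all 6 rigid degrees of freedom.

Default timestep is 15 fs (the standard CG value); the bundled analysis
fixtures use 5–10 fs because their beads are lighter-loaded than a
production solvated system.

## Parameterizing CD pairs by relative-entropy grid search

The model's nonbonded CD parameters are derived by a three-step
grid-search protocol:

1. `evaluate_grid()` runs a short simulation of a single solvated
   nanoparticle for every `(sigma, epsilon)` candidate
   (`interaction_grid()`), measures two features — the radial
   distribution of the solvent and of the terminal ligand-shell beads
   around the core's centre of mass — and scores each against target
   distributions with the relative entropy (Kullback–Leibler divergence)
   `S = sum P ln(P/Q)`, `P` being the candidate model's feature and `Q`
   the target. Empty bins are regularised with an additive `1e-10`
   pseudocount; `S = 0` exactly iff the distributions coincide, and the
   measure is deliberately asymmetric.
2. `fit_surface()` fits each relative-entropy surface with a bivariate
   polynomial whose degree is selected on a held-out 20% of the cells by
   test mean-squared error (ties toward the lower degree); the final
   coefficients of the selected degree are then refit on all cells.
3. `combine_surfaces()` evaluates the fitted surfaces on a 10x-upsampled
   grid, normalises each by its element count and sums them;
   `select_optimum()` convolves the combined matrix with a 3x3 mean
   kernel (edge cells average over existing neighbours; exact ties break
   toward the lowest epsilon, then the lowest sigma) and returns the
   smallest smoothed cell.

The feature distributions are the density-normalised RDF curves
themselves scaled to unit mass over the bins, *not* raw distance
histograms: the `r^2` volume factor of a distance histogram would let
featureless bulk bins dominate the divergence and drown the structured
contact region that actually carries the parameter information.

Three optional fit refinements address the awkward geometry of real
relative-entropy surfaces, which can span several orders of magnitude
across a grid (a 10% oversized sigma in a dense fluid is
catastrophically bad, a 25% undersized epsilon only mildly so):
`transform = "log"` fits the polynomial to `log(S)` so divergent cells
do not dominate the least-squares loss; `clip_quantile` caps the top
scores before fitting, since a cell that is 1000x worse carries no more
gradient information about the minimum's location than one 10x worse;
and `log_epsilon = TRUE` uses `log(epsilon)` as the regression
coordinate — epsilon is a positive scale parameter, divergence valleys
are more symmetric in its logarithm, and a quadratic fitted to a skewed
valley otherwise places its vertex systematically off the true minimum.
All three default off; the identity-scale plain polynomial remains the
reference behaviour.

`boltzmann_invert()` supplies the bonded terms: the equilibrium value is
the distribution mode and the force constant comes from a quadratic fit
of `-kB T ln p` around the mode (angle histograms are first corrected by
the `sin(theta)` Jacobian). Multimodal inputs are flagged via the modes
of a kernel density estimate; flat inputs are flagged when the implied
well depth across the sampled range is below `kB T / 2`.

### What the recovery experiment shows — and what it does not

The package validates the whole pipeline end to end by planting a known
optimum and recovering it: a small rigid nanoparticle (8 Au + 10 CD on a
0.45 nm shell, 10 OT ligands) in a box of 150 weakly self-interacting
probe-solvent beads, with the CD:W pair set to `sigma* = 3.8 Å`,
`epsilon* = 5 kJ/mol` at the centre of a 5x5 grid (±10% in sigma, ±50%
in epsilon). Targets are generated by the same engine at the true cell
with an independent seed (four averaged replicas; two per grid cell),
and the surfaces are fitted with the quadratic log-scale model in
`(sigma, log epsilon)` coordinates with the top decile of scores capped
(`transform = "log"`, `log_epsilon = TRUE`, `clip_quantile = 0.9`).
Recovery must land within half a grid step on both axes.

The state point is deliberately *not* the published one, for reasons
worth understanding when applying the protocol to real systems:

* at liquid density, fluid structure is dominated by packing
  (repulsion): `g(r)` is nearly blind to well depths of a few tenths of
  kJ/mol, and resolving them requires the tens-of-ns, ~10^4-particle
  sampling of a production study. In a dilute probe solvent,
  `g(r) ≈ exp(-beta u(r))` and the contact peak images the CD:W well
  directly, so the information content per simulation step is maximal;
* the probe solvent's self-interaction is reduced (`epsilon_WW = 1.2`
  kJ/mol, supercritical at 298 K) because near-coexistence solvents
  develop slow droplet fluctuations that swamp the feature statistics at
  this scale;
* the whole nanoparticle is held rigid so that the shell feature is
  exactly reproducible; its surface contributes a harmless constant and
  the recovery is driven by the solvent feature. With flexible ligands
  the shell RDF carries slow conformational noise that only long
  production runs average out;
* epsilon* sits at ~2 kT so that the ±50% grid spans a usable dynamic
  range of contact occupancies, and the feature range is restricted to
  the nanoparticle region (`r_max = 1.2` nm) so contact bins carry a
  large share of the distribution mass.

Passing this experiment demonstrates that the machinery — simulation,
feature extraction, divergence scoring, surface fitting, combination,
smoothed selection — locates a planted optimum from dynamics alone. It
does *not* demonstrate that desk-scale runs can re-derive the published
CD parameters against all-atom targets; that calibration needs the
original sampling scale, which is the reason the shipped pair table is
treated as data rather than recomputed.

## Umbrella sampling and WHAM

`generate_windows()` builds the ladder of harmonic windows along the
NP–NP core centre-of-mass distance (default spacing 0.2 nm, default bias
constant 1300 kJ/mol/nm², the same constant used for constant-velocity
pulling). `wham()` runs the standard self-consistent iteration over
window free-energy offsets (default bin width 0.02 nm, offset tolerance
1e-8 kcal/mol) and returns the profile in kcal/mol, zeroed on the
detected plateau. Gaps between window histograms produce a warning, not
silent bridging; per-bin uncertainties are available by block bootstrap
(off by default). The first 10% of each window's samples is discarded as
equilibration.

`analyze_pmf()` extracts the three physical features of a dimerization
profile: the **plateau distance** (inner edge of the outermost run of
bins with |dF/dr| below 0.5 kcal/mol/nm over at least 0.4 nm — both
thresholds are operational definitions of this package and are
configurable), the **primary-minimum depth** relative to the plateau
level, and the **barrier** (the maximum between the minimum and the
plateau, relative to the plateau, floored at zero). All features are
invariant to constant shifts of the profile. `compare_pmf_features()`
turns two profiles' features into the percentage comparisons used when
benchmarking a CG profile against a reference profile, quoted against
the CG value.

The synthetic double-well validation (`U = a (r-r1)^2 (r-r2)^2` sampled
by Metropolis Monte Carlo under each window bias) reconstructs the
potential to better than 0.2 kcal/mol across the sampled range with 15
windows of 10^4 samples.

## Aggregation observables

`detect_clusters()` partitions nanoparticles into connected components
of the contact graph (pairs with minimum-image centre distance below a
cutoff). The published protocol never states the numeric cutoff; the
package records whatever cutoff is used in the trace metadata, and a
practical default is the first minimum after the first peak of the
NP–NP RDF (about 2.6 nm for core-contact aggregation of these
particles). `aggregation_kinetics()` reports the per-frame fraction of
nanoparticles in clusters of size ≥ 2 — "no longer free in solution" —
plus cluster counts and size histograms.

`fit_exponential()` fits the saturating form `f(t) = A (1 - e^(-t/tau))`
— chosen because the aggregated fraction is a bounded growing quantity,
so the plateau `A` reads off the fraction of particles that will
eventually aggregate. `convergence_extrapolation()` evaluates the fitted
curve at a longer horizon and declares convergence when the predicted
change from the end of the trace is below a threshold (default 0.01).

## Synthetic fixtures

All tests and tutorials run from generators shipped in the package (no
external data): ideal-gas frames (the exact `g(r) = 1` null), a 1-D
Metropolis Boltzmann sampler (the oracle for WHAM and Boltzmann
inversion), closed-form Gaussian feature surrogates for fast pipeline
tests (peak position tracks sigma, width tracks epsilon,
monotonically), and saturating-exponential aggregation traces. Every
fixture is seeded and bit-reproducible.

What the fixtures do **not** emulate: all-atom reference data,
long-time conformational relaxation of the ligand shell,
pressure-coupled (NPT) ensembles, and mesh electrostatics. Test results
therefore validate correctness of the algorithms at desk scale, not
production-scale thermodynamics.

## Problem sizes used by the test-suite and acceptance script

The bundled validations use: 200-bead LJ fluids (10^4 NVE steps at 5 fs)
for energy conservation; 15 umbrella windows x 10^4 Monte-Carlo samples
for WHAM; a 5x5 grid x 2 replicas x 15000 steps of a ~230-bead solvated
nanoparticle for grid recovery; 200 random configurations for the
cluster-partition cross-check; and 10^3 random distribution pairs for
the divergence properties. These sizes were chosen as the smallest at
which each property is decisively resolved above its sampling noise.

## Known limitations

* NVT/NVE only (no barostat); densities are set by construction.
* DSF point-charge electrostatics with scalar dielectric — adequate for
  the screened, ion-paired systems the model targets at desk scale, but
  not a PME replacement.
* The rigid-body Langevin update thermostats angular momentum in the
  lab frame per step; extremely aspherical cores with near-singular
  inertia would need smaller steps.
* The generated core is an approximation with the correct bead counts
  and shell radius, not a crystallographic Au144(SR)60 structure; import
  coordinates where that matters.
* Desk-scale aggregation runs (a few NPs, ns) illustrate the analysis
  chain; published-scale kinetics (27 NPs, microseconds) are out of
  scope.
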