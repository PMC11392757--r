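---
title: "Methods: Fab crosslinker rigidity, interface stability, and SAXS shape analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Fab crosslinker rigidity, interface stability, and SAXS shape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fabflex)
```

# Scope and units

fabflex implements the structural-analysis layer for comparing how
bivalent antibody fragments crosslink cell-surface receptors: a
non-covalent Fab dimer (two Fabs associating via their constant-domain
C-termini) against a hinged, covalent F(ab')2. Three questions drive the
design: how rigid is the Fab-Fab geometry over an MD trajectory, is the
Fab-Fab interface energetically stable, and what receptor-receptor
geometry does a near-linear crosslinker impose across membranes. A SAXS
stack connects model shapes to solution scattering.

All interfaces use Angstrom for coordinates, ns for time, kcal/mol for
energies, and degrees for angles. Residue numbering is author (1-based)
PDB numbering; ranges are inclusive on both ends.

# Fab-Fab angle statistics

Each Fab is reduced to an axis: the vector from the center of mass of its
constant domain to the center of mass of its variable domain. The Fab-Fab
angle is the unsigned angle between the two axes, in [0, 180] degrees; no
dihedral or sign convention is attached, matching how such angles are
reported as scalars. Over a trajectory, `angle_series()` evaluates the
angle per frame and summarizes the frames whose timestamps fall inside a
window (default 20-100 ns, both endpoints inclusive, frames selected by
timestamp rather than index): mean, standard deviation with the n-1
denominator, and range (max minus min). The first ~20 ns of a production
run are treated as residual equilibration, hence the default window.

Group rigidity contrasts use a two-sample two-tailed t-test on per-model
angle SDs (`compare_angle_sd()`). The pooled equal-variance form is the
default because that is the plain reading of "two-tailed t-test" in this
setting; Welch's correction is available by flag. Degenerate input (both
groups constant and equal) returns p = 1 rather than an error.

# Rigid-body superposition and grafting

`kabsch_fit()` computes the proper rotation and translation minimizing
weighted RMSD via the SVD of the covariance matrix, with the reflection
branch corrected so det(R) = +1. Collinear point sets are rejected: the
in-plane rotation is then not unique, and silently returning one of
infinitely many solutions would poison downstream grafting. Tests
cross-check against an independent Horn quaternion implementation.

`graft_structure()` assembles composite models through shared atoms: the
ligand's shared selection is superposed onto the target's, the whole
ligand is transformed, and the assembly keeps the target's copy of the
shared atoms. The fit RMSD is reported and a warning is raised above 1.8
Angstrom, the acceptance bound used when attaching antibody fragments to
receptor models through shared C-alpha coordinates. Inter-body clashes
(closer than 1 Angstrom) are reported as messages, not errors - a clash
is a modelling smell, not an algorithmic failure.

# Transmembrane vectors

A receptor's membrane orientation is summarized by a TM vector: per
transmembrane helix, the vector from its first-residue C-alpha to its
last-residue C-alpha; the bundle TM vector is the normalized sum over
helices. The phrase "vector sum of the first and last transmembrane helix
C-alpha coordinates" admits more than one reading; this per-helix
first-to-last construction is adopted because coordinates alone carry no
direction, and a sum of per-helix axis vectors is the only variant that
yields one. The angle between two receptors' TM vectors is reported in
[0, 180] degrees: 0 means both receptors point the same way (compatible
with one membrane), 180 means opposing parallel membranes - the geometry
of a crosslinker bridging two cells.

# Contacts and interface energetics

Atoms are in non-covalent contact within 2.0 Angstrom. Hydrogens are
included by default (the MD systems this emulates are all-atom); at 2
Angstrom an all-atom cutoff effectively selects hydrogen bonds and salt
bridges. Persistence follows the windowed rule: trajectories are cut into
1 ns windows, a pair is persistent in a window when in contact for at
least half of that window's frames (boundary inclusive), and pairs are
ranked by total persistent time. Contact detection uses a cell-list grid
with cells of one cutoff length, which prunes only pairs strictly beyond
the cutoff, so results are identical to the all-pairs scan (a property
the tests check on 200 random configurations).

Inter-group energies are the plain pairwise sums: Coulomb with k =
332.0636 kcal A/(mol e^2) and a 12-6 Lennard-Jones in epsilon/Rmin form
with Lorentz-Berthelot combining. The default 9 Angstrom cutoff truncates
sharply; there is no Ewald/long-range correction and no periodic-boundary
minimum-image handling - inputs must be whole, imaged molecules. These
sums are analysis estimators over trajectory frames, not simulation
forces.

The linear interaction energy score is `E_LIE = 0.5 E_elec + 0.18
E_vdw`. The 0.18 vdW coefficient is the formal definition used here; a
0.15 variant appears in some interface-plot conventions and both are
exposed as configuration. An interface is classified dissociated when the
mean LIE over the final fifth of the trajectory (by time) is positive -
an operationalization of "ends with positive interaction energy" that is
robust to early transients; the tail fraction is configurable.

# SAXS analysis

`debye_profile()` computes I(q) = sum_ij f_i f_j sinc(q r_ij) with unit
point form factors, at atom or residue (one bead per residue center of
mass) granularity. This is shape-only modelling: it reproduces Rg, Dmax
and compactness signatures, which is all the package's comparisons need;
real-form-factor fitting with excluded-volume terms is out of scope.

`guinier_fit()` performs weighted linear least squares of ln I versus q^2
on the largest low-q window satisfying q_max * Rg <= 1.3, found by
iterating fit, recompute Rg, re-trim until self-consistent, starting from
the lowest 25% of points. Weights are (I/sigma)^2 when errors are present
(the delta-method variance of ln I); non-positive intensities are dropped
with a warning and fewer than five surviving points is an error. A known
limitation documented here deliberately: on an exactly spherical
scatterer the q Rg <= 1.3 window overestimates Rg by about 1.7-1.8%
(the sphere form factor falls slightly faster than the Gaussian inside
the window). This is a property of the standard procedure, not of the
implementation; narrowing the window reduces the bias at the cost of
noise sensitivity, and the default stays at the conventional 1.3.

The dimensionless Kratky transform plots (qRg)^2 I/I(0) against qRg. An
ideal Guinier scatterer peaks at the Guinier-Kratky point (sqrt(3), 3/e
= 1.104); compact globules peak near it, extended or flexible shapes
shift up and to the right. The reported peak is the grid maximum, so its
abscissa resolution is the q-grid spacing.

P(r) is computed structure-side only, as the normalized histogram of
pairwise bead distances, with Dmax the exact (unbinned) maximum pairwise
distance. Regularized indirect inversion of experimental data is a
different, ill-posed problem and is intentionally not implemented.

The Porod invariant Q = integral q^2 I dq uses an analytic Guinier
extension on [0, q_min], the trapezoid rule on the data, and no high-q
extrapolation; when q^4 I has not plateaued by the end of the data a
truncation warning is emitted (Q biased low, Vp high - about +5% for a
solid-sphere profile truncated at q = 0.75/A). Vp = 2 pi^2 I0/Q, and the
globular-protein mass estimate is MM[kDa] = Vp[nm^3]/1.6, with the
Angstrom-to-nm^3 conversion handled explicitly.

The chi-square fit uses the printed convention chi^2 = 1/(n-1) sum_j
[(I_exp - c I_calc)/sigma_j]^2 with the closed-form optimal scale c =
sum(I_exp I_calc/sigma^2)/sum(I_calc^2/sigma^2); the n-1 denominator is
kept exactly as printed even though plain n is more common elsewhere.
Model curves are linearly interpolated onto the experimental grid;
extrapolation is forbidden. Concentration-series merging scales the
low-concentration profile onto the high-concentration one by weighted
least squares over the overlap (a fitted rather than fixed scale, the
natural choice when the true ratio is unknown) and splices at the overlap
midpoint.

NSD between bead models follows the Kozin-Svergun construction: one-sided
mean squared nearest-neighbour discrepancies, each normalized by the
partner set's mean nearest-neighbour spacing, averaged and square-rooted;
0 for identical sets, near 1 for superimposable similar shapes.

Ensemble selection is a deliberately simplified stand-in for
genetic-algorithm ensemble optimization: non-negative least squares on
error-whitened intensities over a pool of model curves, followed by
simplex normalization, with the joint scale reported separately. The
weighted SD of the member Rg distribution is reported as an explicitly
named flexibility proxy; it is not numerically comparable to published
R_flex/R_sigma metrics, whose formulas are not re-derived here.

# Synthetic data: what it emulates, what it does not

Every generator embeds its ground truth and takes an explicit seed
(`withr::with_seed`, so the global RNG state is untouched):

- `make_fab_dimer()` builds two-domain C-alpha bead Fabs (unit masses)
  with the printed chain layout - light chain residues 1-213, heavy chain
  214-432, chains L/H and B/A - and an exactly constructed inter-Fab
  angle. Defaults give 432 residues per Fab, 864 per dimer.
- `make_angle_trajectory()` rotates Fab 2 rigidly about its hinge so the
  per-frame angle follows a stated Gaussian (draws clamped to [1, 179]
  with the clamp count reported). Defaults: mean 130, SD 5, 106 frames at
  1 ns - the length of a production MD run.
- `make_membrane_pair()` builds two eight-helix bundles with exact TM
  vectors (19-residue ideal helices, five full turns, so the first-to-last
  CA vector lies exactly on the axis) about 150 A apart.
- `make_scatter_profile()` provides the ideal Guinier curve, the exact
  sphere form factor, and a Debye curve of a two-lobe bead dimer whose
  maximum dimension is exact by construction (each lobe carries an
  outer-pole bead); noise is multiplicative Gaussian with the stated CV,
  and the error column records that truth.
- `make_energy_series()` and `make_contact_trajectory()` script the LIE
  plateau/drift and per-window contact occupancies frame-exactly.

These fixtures are geometric and statistical stand-ins. They do not
mimic force-field dynamics, solvent, correlated frame-to-frame motion,
realistic SAXS form factors, or instrument backgrounds. Passing the
recovery tests therefore demonstrates that the analysis layer measures
what it claims to measure on data with known truth - not that any
particular biological system behaves this way.

# Numerical choices and degenerate inputs

- Kabsch: collinear or sub-3-point input errors; weights must be
  non-negative with positive sum.
- Angle computations clamp cosines into [-1, 1] before acos; zero-length
  domain or TM vectors are errors, never NaN.
- Guinier window iteration caps at 100 rounds with cycle detection; the
  flat-profile limit returns Rg = 0.
- Contact occupancies use a half-open window assignment
  (floor((t - t0)/w), with a 1e-9 guard against timestamp round-off);
  a trajectory shorter than one window is a single truncated window with
  a warning.
- The dissociation verdict is a strict "> 0" on the tail mean: an
  interface exactly at zero is called stable.
- NNLS (via `pracma::lsqnonneg`) can return an all-zero solution on
  pathological pools; this is an error, not a silent zero ensemble.

# Problem sizes in the shipped analyses and tests

The numbered scripts under `analysis/` and the test suite use scaled-down
but structurally faithful problems chosen for tight feedback loops: 5 + 5
trajectory models of 106 frames for the rigidity contrast, bead models of
a few hundred to 2000 beads for SAXS recovery, and 200-configuration
oracle sweeps for the grid/contact equivalence. These sizes were chosen
so the full suite exercises every code path in well under a minute per
file while keeping sampling errors far smaller than the tolerances being
asserted.
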