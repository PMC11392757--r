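# fabflex

Structural analysis of bivalent antibody fragments as receptor
crosslinkers, in R.

A non-covalent dimer of two Fab fragments (a "Bi-Fab", associating via
its constant-domain C-termini) can crosslink cell-surface receptors such
as CD3 on T cells much the way a covalent, hinged F(ab')2 does — but the
two differ sharply in rigidity, and that difference shapes what geometry
they can impose on the receptors they bridge. fabflex implements the
analysis layer for making that comparison quantitative, for anyone with
MD trajectories, docked models, or solution-scattering curves of
antibody fragments:

- **Fab–Fab angle statistics.** Each Fab is reduced to the vector from
  its constant-domain center of mass to its variable-domain center of
  mass; the Fab–Fab angle is the angle between the two vectors. Over a
  trajectory, `angle_series()` reports per-frame angles and the mean, SD
  (n−1) and range (Δ) over a time window (default 20–100 ns), and
  `compare_angle_sd()` runs the two-tailed t-test between model groups.
- **Interface persistence and stability.** `contact_persistence()`
  applies the 2 Å / 1 ns-window / at-least-half occupancy rule and ranks
  atom pairs by persistent time; `nonbonded_energy()` and `lie_energy()`
  score the interface with the linear interaction energy
  E_LIE = 0.5 E_elec + 0.18 E_vdW, and `classify_association()` calls an
  interface dissociated when the tail-mean LIE turns positive.
- **Bridge geometry.** `kabsch_fit()`/`graft_structure()` assemble
  receptor–crosslinker–receptor models through shared atoms (warning
  above 1.8 Å RMSD), and `tm_vector()`/`tm_angle()` measure the angle
  between the receptors' transmembrane vectors: ~0° is compatible with a
  single membrane, angles approaching 180° force opposing, parallel
  membranes — i.e. crosslinking between two cells.
- **SAXS stack.** Debye model curves from coordinates, Guinier fits on
  the self-consistent q·Rg ≤ 1.3 window, dimensionless Kratky transforms
  (ideal globule peak at (√3, 3/e ≈ 1.104)), structure-side P(r) with
  exact Dmax, Porod volume with MM[kDa] = Vp[nm³]/1.6, the χ² fit with
  the 1/(n−1) normalization and closed-form scale, concentration-series
  merging, NSD between bead models, and a simplified NNLS ensemble
  selection.
- **Synthetic data with ground truth.** `make_fab_dimer()`,
  `make_angle_trajectory()`, `make_membrane_pair()`,
  `make_scatter_profile()`, `make_energy_series()` and
  `make_contact_trajectory()` generate every input class with embedded
  truth (exact angles, exact Dmax, scripted occupancies, labeled
  stability), so the whole stack is testable offline.

Units everywhere: Å, ns, kcal/mol, degrees.

## Worked example

Generate a stiff and a hinged Fab-dimer trajectory with known angle
distributions, and compare their windowed flexibility:

```r
library(fabflex)

stiff  <- make_angle_trajectory(angle_mean = 150, angle_sd = 3,
                                n_frames = 106, dt_ns = 1, seed = 101)
hinged <- make_angle_trajectory(angle_mean = 130, angle_sd = 15,
                                n_frames = 106, dt_ns = 1, seed = 201)

s <- summary(angle_series(stiff$trajectory,  stiff$fab1,  stiff$fab2))
h <- summary(angle_series(hinged$trajectory, hinged$fab1, hinged$fab2))
str(s)
#> List of 5
#>  $ mean     : num 150
#>  $ sd       : num 3.18
#>  $ range    : num 14.8
#>  $ n        : int 81
#>  $ window_ns: num [1:2] 20 100
c(stiff = s$sd, hinged = h$sd)
#>     stiff    hinged
#>  3.176758 14.772908
```

The stiff dimer samples a ~3° spread over the 20–100 ns window where the
hinged one samples ~15°: the contrast the windowed SD/range statistics
are built to expose. The same flow on a SAXS profile:

```r
sp <- make_scatter_profile("guinier", rg = 43.17, i0 = 7)
g  <- guinier_fit(sp$profile)
g
#> <guinier_result> Rg 43.170 A, I0 7, 20 points, q 0.0015-0.03
k <- kratky_dimensionless(sp$profile, g)
round(c(attr(k, "peak_qrg"), attr(k, "peak_value")), 4)
#> [1] 1.7484 1.1034    # the Guinier-Kratky point (sqrt(3), 3/e), at the
#>                      # default 200-point grid resolution
```

## Analysis workflow

The `analysis/` directory holds four numbered narrative drivers, each a
thin script over the package functions, writing tidy CSV/JSON tables
under `results/`:

| script | what it shows |
| --- | --- |
| `analysis/01_fab_flexibility.R` | 5 stiff vs 5 hinged trajectory models; windowed SD/range per model; group t-test (prints mean SDs 4.2° vs 14.6°, p ≈ 3e-6) |
| `analysis/02_interface_stability.R` | scripted contact schedule → per-window occupancy/persistence; stable vs dissociating LIE fixtures and their verdicts |
| `analysis/03_bridge_geometry.R` | receptor pairs at prescribed inter-membrane angles 101–155°; TM vectors measured back exactly; graft RMSD ≈ 0 |
| `analysis/04_saxs_analysis.R` | Guinier/Kratky/P(r)/Porod/χ²/merge/NSD/ensemble on synthetic curves with truth |

Run them from the repository root after installing, e.g.
`Rscript analysis/01_fab_flexibility.R`.

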