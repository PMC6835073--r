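---
title: "Gaussian accelerated MD at desk scale: boost, reweighting and pose clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian accelerated MD at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gamdtk)
```

## The problem this package addresses

Peptide-protein complex structures produced by global docking are
typically medium-quality: the peptide is placed in roughly the right
site but with backbone RMSDs of several Angstrom to the crystal
conformation. Refining such poses with plain molecular dynamics is slow
because the relevant rearrangements are rare barrier-crossing events.
Gaussian accelerated MD (GaMD) addresses this by adding a harmonic
*boost potential* wherever the system's potential energy falls below a
threshold, flattening the landscape enough to accelerate transitions
while keeping the bias well-behaved enough that the unbiased free-energy
surface can be recovered afterwards by *energetic reweighting*. The
refined ensemble is then clustered by pairwise backbone RMSD and the
clusters ranked by reweighted free energy; the top-ranked
representative is the predicted pose.

`gamdtk` implements this entire computational chain — boost-parameter
selection, boosted Langevin dynamics, cumulant-expansion reweighting,
Kabsch-superposition RMSD, hierarchical and greedy pose clustering,
free-energy ranking — at *desk scale*: the dynamics engine runs on
analytic model potentials and a coarse bead-chain "peptide" whose
Boltzmann statistics are exactly computable by quadrature. Every claim
the workflow makes on real systems ("reweighting recovers the PMF",
"boosted runs cross barriers more often") is therefore a *testable
theorem* here, checked against closed forms and independent oracles
rather than against other simulations.

## The boost potential

For potential energy $V(\mathbf r)$ below a threshold $E$, GaMD adds

$$\Delta V(\mathbf r) = \tfrac{1}{2}\,k\,\bigl(E - V(\mathbf r)\bigr)^2,
\qquad V(\mathbf r) < E,$$

and nothing otherwise. Forces on the boosted surface are the plain
forces scaled by $1 - k(E - V)$, so the modified landscape preserves
the *order* of energies ($V + \Delta V$ is non-decreasing in $V$)
whenever $k (E - V_{min}) \le 1$. Writing $k = k_0 / (V_{max} -
V_{min})$ with $k_0 \in (0, 1]$ makes that guarantee structural.

The parameters come from potential-energy statistics
($V_{max}, V_{min}, V_{avg}, \sigma_V$) collected over a conventional
MD (cMD) stage, under the **$\sigma_0$ criterion**: the standard
deviation of the boost must not exceed a user ceiling $\sigma_0$
(default 6 kcal/mol, the established GaMD practice), which is what
keeps the reweighting statistics tractable. Two threshold choices are
implemented:

* **lower bound** (default): $E = V_{max}$ and
  $k_0 = \min\!\bigl(1, \frac{\sigma_0}{\sigma_V}\,
  \frac{V_{max}-V_{min}}{V_{max}-V_{avg}}\bigr)$;
* **upper bound**: $E = V_{min} + 1/k$ with
  $k_0'' = \bigl(1 - \frac{\sigma_0}{\sigma_V}\bigr)
  \frac{V_{max}-V_{min}}{V_{avg}-V_{min}}$, falling back to the lower
  bound whenever $k_0''$ leaves $(0, 1]$.

A *dual boost* applies independent boosts to the dihedral energy
component and to the total potential; the bead-chain model exists
precisely so that this decomposition ($V = V_{dih} + V_{rest}$, forces
exactly $-\nabla V$) is available and testable. On analytic potentials
without a dihedral class a requested dual boost degrades to a total
boost with a warning.

## The staged protocol

`run_protocol()` (and `cmd_simulate()` above it) mirrors the standard
preparation sequence: energy minimization (steepest descent then
conjugate gradient, switched by step count), heating from 0 K to the
target temperature under 1 kcal/(mol Å²) harmonic positional
restraints, a second restrained equilibration, an unrestrained cMD
stage that streams potential statistics, an *adaptive* GaMD
equilibration during which the statistics keep accumulating and the
boost parameters refresh every save interval, and finally independent
production runs with randomized initial velocities that share the
frozen parameters and differ only by seed.

Two protocol-fidelity notes. First, the reference workflow includes a
constant-pressure equilibration stage; toy systems have no solvent or
box, so that stage is replaced by a second constant-volume
equilibration of the same length. Second, the reference stage ratio
(statistics : boost equilibration : production = 2 : 18 : 300 ns) is
*not* preserved literally: at desk scale what matters is that the
adaptive equilibration actually visits the barrier region so that the
frozen threshold $E$ reflects the full energy range — with a strictly
scaled-down ratio it does not, and production enhancement collapses.
The default schedule (5k steps of cMD statistics, 250k of adaptive
GaMD equilibration, 4 × 600k production at dt = 2 fs) was sized from
that convergence requirement. Statistics accumulate across the
cMD-to-GaMD boundary rather than resetting, which is the simplest
consistent reading of an "equilibration after applying the boost".

The integrator is BAOAB Langevin splitting, chosen for its
configurational accuracy at practical step sizes; with zero friction it
reduces to velocity Verlet, which the test suite uses for an NVE
energy-conservation check. Friction defaults to 1 ps⁻¹, the
conventional Langevin collision frequency in biomolecular packages.
Units are kcal/mol, Å, ps, amu, K throughout, with
$k_B = 0.0019872041$ kcal/(mol K).

One numerical guard: with $k_0 = 1$ the boosted landscape has zero
slope exactly at the recorded $V_{min}$; a production frame that dips
*below* the frozen $V_{min}$ would see a negative force factor (an
energy-ordering inversion). The engine clamps the factor at 0 for such
excursions and counts them in the trajectory metadata
(`n_factor_clamped`); under the default conditions they are rare to
absent.

## Energetic reweighting

A boosted run samples $p^*(x) \propto e^{-\beta (V + \Delta V)}$ along
a reaction coordinate $x$. The unbiased density follows by weighting
each frame with $e^{\beta \Delta V}$; per histogram bin,

$$F(x) = -\tfrac{1}{\beta}\Bigl[\ln p^*(x) +
  \ln\bigl\langle e^{\beta \Delta V}\bigr\rangle_x\Bigr] + C.$$

`pmf_exponential()` evaluates the bin-conditional average exactly (in
log space, so large boosts cannot overflow); it is algebraically
identical to brute-force per-sample importance weighting, and a test
pins that equality to 1e-10. Because the exponential average has heavy
tails, the production estimator is `pmf_cumulant()`, the truncated
cumulant expansion

$$\ln\langle e^{\beta\Delta V}\rangle \approx
  \beta C_1 + \tfrac{\beta^2}{2} C_2 + \tfrac{\beta^3}{6} C_3,$$

with $C_1$ the bin mean, $C_2$ the population variance and $C_3$ the
third central moment of $\Delta V$ in the bin. Order 2 (the default,
matching standard reweighting practice) is exact when the
bin-conditional boost is Gaussian. Bins below a minimum count (default
10; third moments are unstable below that) are masked — reported as
missing, never as zero — and masked bins do not participate in the
shift that places the occupied minimum at 0.

The `anharmonicity()` diagnostic is the entropy deficit of the
$\Delta V$ distribution relative to a Gaussian of equal variance:
$\gamma = S_{Gauss}(\sigma) - S_{data} \ge 0$, zero exactly for
Gaussian boosts. One honest limitation: near-Gaussianity of the
*global* $\Delta V$ distribution arises from summing many
quasi-independent degrees of freedom. On the 1D double well, $\gamma$
is therefore substantial (~0.4) even though per-bin reweighting is
essentially exact there ($\Delta V$ is a deterministic function of the
coordinate, so bin-conditional variances are tiny); the near-Gaussian
regime appears on the many-dof bead chain, and that is where the suite
tests it. On real all-atom systems — the regime the method targets —
the global $\gamma$ is the meaningful accuracy certificate.

## Geometry and clustering

`read_pdb()`/`write_pdb()` handle fixed-column PDB with MODEL stacks
(parsing via bio3d; alternate locations reduce to the
highest-occupancy conformer, first altloc on ties). The backbone
convention is N, CA, C — the common CPPTRAJ/CAPRI choice; the carbonyl
O can be included by argument. `kabsch_superpose()` is a standard SVD
Kabsch with the determinant sign correction (always a proper
rotation); `ligand_rmsd()` implements the CAPRI-style convention — fit
on the receptor backbone, measure the peptide backbone without
refitting — with atom correspondence by residue number and atom name,
and mismatches rejected with a paired diff. Whether published peptide
RMSDs were receptor-fitted or peptide-fitted is often unstated; both
are available (`rmsd_fit()` for the direct fit) with the CAPRI style
as default.

Two clustering algorithms cover the two stages of the docking-plus-MD
workflow. `hier_agglom_cluster()` is bottom-up agglomeration on the
pairwise RMSD matrix halted when the minimum inter-cluster linkage
exceeds the cutoff (3.5 Å backbone RMSD by convention); average
linkage is the default, as in CPPTRAJ, with single/complete
selectable. The implementation delegates the linkage computation to
`stats::hclust` and a cutoff cut; a test verifies the partition against
a naive O(n³) textbook agglomeration. `greedy_cluster()` is the
fragment-clustering greedy algorithm (0.5 Å radius by convention):
repeatedly seed a cluster at the item with the most neighbors within
the radius, lowest index on ties. Representatives are medoids.

`rank_clusters()` ranks by size (docking stage) or by reweighted free
energy: each cluster's reweighted population $p_c = \sum_{i \in c}
e^{\beta \Delta V_i} / \sum_i e^{\beta \Delta V_i}$ gives $F_c =
-k_B T \ln p_c$, shifted so rank 1 reads exactly 0.00. With zero boost
this reduces *exactly* to population ranking. A published per-cluster
"PMF" can also mean the PMF-surface value at the cluster's
coordinates; the population form is implemented because it is
well-defined without choosing a surface, and the alternative can be
read off any `pmf_grid` at the representative's coordinates.

## What the synthetic fixtures emulate — and what they do not

`make_pose_ensemble()` draws frames around perturbed copies of a
reference structure: each planted cluster is a fixed random per-atom
displacement with a prescribed unfitted RMSD, plus isotropic Gaussian
noise per frame, with ground-truth labels stored alongside. It
emulates the *shape* of a refined ensemble — a dominant near-native
cluster plus decoys at known separations — which is exactly what the
clustering-recovery and ranking tests need. It does not emulate
physical correlations: displacements are not volume-excluding, noise
is isotropic rather than mode-structured, and cluster populations are
i.i.d. draws rather than kinetically correlated visits. Passing tests
on these fixtures validate the *analysis machinery*, not force-field
realism.

Likewise the double well and four-well surfaces stand in for
free-energy landscapes along RMSD-like coordinates, and the bead chain
for a molecule with a separable dihedral energy class; none of them
model solvent, electrostatics or real peptide energetics
(deliberately — see Non-goals in the README).

## Problem sizes and numerical choices

The default study conditions were fixed from convergence diagnostics
(barrier transitions observed, threshold-E stability during
equilibration): asymmetric double well with 6 kcal/mol barrier and
2 kcal/mol tilt at 310 K, mass 12 amu, dt 2 fs, friction 1 ps⁻¹,
frames every 100 steps; 4 production runs of 600k steps pooled for
reweighting (~24,000 frames). At these sizes the full protocol plus
reweighting runs in about two minutes on one CPU. The quadrature
oracle integrates each bin on its own local trapezoid grid and doubles
the refinement until the PMF changes by less than 0.01 kcal/mol
(configurable), erroring rather than truncating if it cannot converge.
Histogram bins default to 0.1 Å for toy coordinates and 0.5 Å for RMSD
coordinates; 2D grids are capped at 200 × 200 bins.

Residual PMF-recovery error on the double well is dominated not by the
cumulant truncation (per-bin $\Delta V$ is nearly deterministic in 1D)
but by the finite number of inter-well transitions, which sets the
statistical error of the well-to-well free-energy difference; it
scales roughly as $2 k_B T / \sqrt{n_{trans}}$ and motivates the
default production length.

## Known limitations

* No pressure coupling, constraints, cutoff/PME electrostatics, or
  replica methods; the engine is a toy-scale NVT/NVE integrator by
  design.
* Free-energy ranking assumes pooled frames are equally weighted
  draws; no per-run reweighting or kinetic (rate) information is
  recovered.
* The anharmonicity certificate is informative only for many-dof
  systems (above).
* Atom correspondence for RMSD is by residue number and atom name;
  there is no sequence-alignment-based mapping and no mmCIF input.
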