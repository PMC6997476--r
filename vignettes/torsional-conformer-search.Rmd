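---
title: "Torsional conformer searching and multi-structural partition functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Torsional conformer searching and multi-structural partition functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torsconf)
```

## Scope and model

`torsconf` locates the torsional conformers of flexible *acyclic*
molecules: local minima of the potential energy surface reachable by
internal rotation about the `t` user-declared target torsions of a
Z-matrix.  The coordinates of the search are the torsional points
$\Phi = (\phi_1, \dots, \phi_t)$, each angle stored in degrees on
$[0, 360)$; all other internal coordinates are fully relaxed during
optimization but play no role in identity decisions.  Two structures are
"the same conformer" exactly when all their target torsions coincide
within a tolerance — there is no RMSD or permutation-aware matching, and
ring puckering, inversion and other non-torsional conformational motion
are out of scope.

The search combines two engines that share one screening pipeline:

* a **systematic phase** over the Cartesian product of per-torsion
  *preconditioned* angles (positions where chemistry expects wells:
  anti/gauche $\{180°, 60°, 300°\}$ for sp³ chains by default), and
* a **stochastic phase** of Monte Carlo cycles drawing $\Phi$ uniformly
  on the torus, organized in batches that may use different hypercube
  sizes.

Every guess must pass, in order: the *connectivity test* (its 0/1
adjacency matrix, built from covalent radii, must equal the reference
geometry's — this discards superimposed atoms and rearranged or strained
structures) and the *similarity test* (it must escape the hypercube of
half-edge $d$ around every stored point; escape means at least one
torsion further than $d$ away on the circle).  A surviving guess is
promoted to a trial, stored, and optimized.  The optimized structure must
pass connectivity again, the *redundancy test* (it must not coincide with
a known equilibrium within `eps_red` in every torsion) and finally the
*Hessian test*.  The order is part of the contract: the Hessian — the
expensive step with a real electronic-structure backend — is computed
only after the two cheap tests have passed, so duplicates never cost a
frequency calculation.

During the systematic phase the similarity test consults the accepted
equilibria only: the preconditioned grid is spaced so that the hypercubes
around its points do not overlap (120° spacing versus the default
$d = 30°$).  During the stochastic phase the full stored pool (trials and
equilibria) applies, since a random point may fall into the area of
influence of a trial that never became a conformer.  The bookkeeping
identity $P = K_1^\star + K_2^\star + J$ — stored points are promoted
trials plus accepted conformers — holds after every event and is asserted
in the test suite over a 1000-cycle fuzzed run.

### Conformational enantiomers

For a molecule with a plane of symmetry, the mirror image of the
conformer at $\Phi$ is the conformer at $-\Phi$ (each angle replaced by
$360° - \phi$), with identical energy, frequencies and principal moments
of inertia.  With `has_sym_plane = TRUE` the systematic pool keeps one
representative per pair — $(K_1+1)/2$ points for reflection-closed
three-angle lists — and, by the same logic, the similarity and redundancy
pools are augmented with the enantiomers of their members, so neither
phase wastes optimizations on mirror images.  `expand_enantiomers()`
regenerates the partners afterwards (mirrored Cartesian coordinates,
identical scalars), giving $2J - n_{self}$ distinguishable structures.
The enantiomer weight $w_j \in \{1, 2\}$ recorded per conformer makes the
weighted thermodynamic sums over $J$ structures exactly equal to the
explicit sums over all $2J - n_{self}$.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `d` | 30 | deg | similarity hypercube half-edge; strictly below half the 120° spacing of the preconditioned wells so systematic hypercubes never overlap; per-batch override in the stochastic phase |
| `eps_red` | 3 | deg | redundancy coincidence tolerance; well above optimizer convergence noise, far below well spacing |
| `eps_freq` | 5 | cm⁻¹ | how negative a projected wavenumber may be before a structure is rejected as a saddle; absorbs finite-difference noise |
| `k_bond` | 1.3 | – | bond-perception scale on the sum of covalent radii (bundled Cordero table) |
| `gtol` | 1e-6 | kcal/mol/Å | optimizer convergence on the largest gradient component |
| `lambda_zpe` | 1 | – | quasi-harmonic frequency scale factor; 0.951 is a typical literature calibration for Hartree–Fock-quality frequencies |
| `seed` | – | – | seeds R's RNG; identical seed and configuration reproduce every output byte for byte |

No reference criterion exists in the literature of this algorithm family
for the bond-perception rule or for the numerical tolerances of the
redundancy and Hessian tests, so these are package choices, recorded in
the run metadata of every run for reproducibility.

## The model surfaces and what they do (not) show

Real applications delegate energies, gradients and Hessians to an
electronic-structure program through the backend contract
(`external_pes_adapter()` ships as the hook; no quantum-chemistry driver
is bundled).  For development, testing and demonstration the package
bundles analytic chain-molecule surfaces (`toy_chain_pes()`): harmonic
restraints hold bonds and angles at their Z-matrix values, and each
target torsion carries a cosine series
$\sum_k a_k (1 + \cos(n_k \phi - \gamma_k))$ plus optional localized
Gaussian wells.  The model chain itself (`make_chain_fixture()`) is a
heavy-atom backbone — a united-atom-like alkane/alkanol without explicit
hydrogens — with 1.526/1.43 Å bonds and 115°/111° backbone angles.  The
angles are deliberately a few degrees wider than tetrahedral: at 112°
the gauche⁺/gauche⁻ helix-reversal arrangements of a three-torsion chain
bring the chain ends to 1.77 Å, inside the covalent bonding threshold, so
the connectivity test would veto genuine minima of a surface that has no
steric terms.  At 115°/111° every anti/gauche combination keeps nonbonded
atoms at ≥ 2.0 Å.

The fixtures exercise specific behaviors: single-well and shared-basin
surfaces (redundancy semantics), separable 9- and 27-well grids
(systematic completeness, enantiomer accounting), an off-grid well near
95° whose basin contains no preconditioned angle (only the stochastic
phase can find it), and a low-level/high-level pair with phase-shifted
wells (the staged-refinement workflow, where low-level minima seed
high-level optimizations).

What passing tests on these surfaces *shows*: the enumeration,
screening, bookkeeping, optimization, enantiomer and partition-function
machinery is correct, deterministic, and agrees with an independent
brute-force relaxation of every node of a dense 10° torsional grid.
What it does *not* show: behavior on real quantum-chemistry surfaces —
coupled torsional modes, conformers whose basins deform or merge at
higher levels of theory, optimization failures of real SCF codes, and
steric effects beyond the adjacency veto are not emulated.  Efficiency
statistics measured on the model surfaces (acceptance ratios, conformers
per cycle) carry no quantitative meaning for real molecules.

## Numerical choices

* **Internal → Cartesian.**  Sequential frame construction; dihedral
  sign follows the standard convention in which the anti arrangement is
  180° and the construction/measurement round trip is exact to well below
  1e-8°.  Colinear reference atoms raise an error rather than produce a
  degenerate frame.
* **Optimizer.**  Quasi-Newton (BFGS from `stats::optim`) on all
  Cartesian degrees of freedom with the analytic gradient, restarted
  (rebuilding the curvature estimate) until the largest gradient
  component falls below `gtol`.  Non-convergence discards the trial and
  is logged, it is never an error.
* **Hessians.**  Analytic where a backend provides them, else central
  finite differences of the gradient with a 1e-4 Å step, symmetrized.
  The Hessian test mass-weights, projects out 3 translations and 3
  rotations (5 for linear geometries, detected by a principal moment
  below 1e-6 amu Å²) via an orthonormalized Eckart-style basis, and
  converts eigenvalues to wavenumbers with CODATA-2018 constants.
* **Angles are circular everywhere.**  All angle comparisons
  (similarity, redundancy, self-enantiomer checks, test oracles) use the
  shortest-arc metric, so 355° and 5° are 10° apart; a plain absolute
  difference would tear artificial holes into the torus at the 0/360
  seam.
* **Tie-breaks.**  The enantiomer reduction keeps the first-encountered
  member of each pair in deterministic enumeration order (last torsion
  varying fastest); `canonical_representative()` provides the
  lexicographic canonical form used for pair identity.
* **Population convention.**  The conformer population is
  $\chi_j \propto w_j e^{-G_j/k_BT}$ with
  $G_j = U_j - k_BT \ln(Q^{rot}_j Q^{QH}_j)$, i.e. Boltzmann weighting
  in $-U_j$ — the unique convention under which the populations are the
  per-conformer shares of the MS-QH partition function.  Likewise the
  MS-T(C) sum includes the $w_j$ weights and $e^{-U_j/k_BT}$ factors, so
  that all-unity anharmonicity factors recover MS-QH exactly.
* **Torsional anharmonicity factors** $f_{j,\eta}$ are accepted as
  inputs (defaulting to 1): their internal construction belongs to the
  coupled-torsional potential model of the hindered-rotor literature and
  is not rebuilt here.  Rotational symmetry numbers are likewise
  user-supplied (default 1); point-group detection is out of scope.
* **Electronic degeneracy** is assumed 1 (closed-shell ensembles).

## Problem sizes in the test suite

The suite runs entirely on the bundled surfaces: grids up to 27 wells
(t = 3), stochastic batches up to 1000 cycles in the bookkeeping fuzz,
100 random ensembles in the partition-function identity checks, and a
10°-step brute-force oracle for the minima comparisons.  These sizes keep
the whole suite under a minute while covering every code path; all of
them scale up by configuration, not by code change.

## Known limitations

* Identity is purely torsional: conformers differing only in
  non-torsional coordinates are not distinguished.
* No automatic detection of rotatable bonds or of the symmetry plane;
  both are declared by the user, and an angle list that is not
  reflection-closed combined with `has_sym_plane = TRUE` is an error.
* Linear molecules are rejected by the rotational partition function
  (three positive moments required).
* The stochastic phase guarantees nothing: a fixed cycle budget bounds
  the work, and even a run that stops adding conformers may have missed
  some.  An optional stop-when-quiet rule is deliberately not the
  default, since any threshold is arbitrary.
* No parallel execution of optimizations.
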