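# torsconf

Conformer searching for flexible acyclic molecules, and the
multi-structural partition functions that the located ensemble feeds.

## The problem

A molecule with *t* freely rotatable single bonds lives on a
*t*-dimensional torus of torsional angles **Φ** = (ϕ₁, …, ϕ_t).  Each local
minimum of the potential energy surface on that torus is a conformer, and
thermochemistry at medium and high temperatures needs *all* of them, not
just the global minimum.  `torsconf` implements a combined strategy:

1. **Systematic search.**  Chemically intuitive guess angles per torsion
   (anti/gauche, `{180°, 60°, 300°}` for sp³ chains) are combined into a
   pool of K₁ = Π P_τ structures.  For a molecule with a plane of symmetry,
   conformers come in enantiomeric pairs {**Φ**, −**Φ**} with identical
   scalar properties, so only (K₁+1)/2 representatives are optimized and
   the mirror structures are generated afterwards.
2. **Stochastic (Monte Carlo) search.**  Random torsional points are drawn
   uniformly, discarding any that fall inside a hypercube of half-edge *d*
   around a previously stored point, so the already explored region of the
   torus is never revisited.  Batches with different *d* can be chained.

Every guess must pass a **connectivity test** (its covalent-radius
adjacency matrix must equal the reference one) and the hypercube
**similarity test** before being optimized; every optimized structure must
pass connectivity, a **redundancy test** against the known equilibria, and
a **Hessian test** (all 3N−6 vibrational wavenumbers real) — in that order,
so no Hessian is ever computed for a duplicate.

The accepted ensemble {U_j, ω_{m,j}, I_j, σ_j, w_j} then yields
multi-structural rovibrational partition functions

    Q^MS-QH = Σ_j w_j Q_j^rot Q_j^QH exp(−U_j / k_B T)

with the rigid-rotor Q_j^rot, the quasi-harmonic Q_j^QH (frequencies scaled
by λ^ZPE), enantiomer weights w_j ∈ {1, 2}, conformer populations
χ_j ∝ w_j exp(−G_j / k_B T) with G_j = U_j − k_B T ln(Q_j^rot Q_j^QH), and
the coupled-torsional MS-T(C) variant that multiplies each conformer term
by user-supplied anharmonicity factors Π_η f_{j,η}.

Electronic-structure calculations are abstracted behind a backend
contract: bundled analytic chain-molecule model potentials make the whole
loop runnable and testable offline, and `external_pes_adapter()` is the
hook for real quantum-chemistry programs.

## Worked example

A butanol-like model chain with three target torsions on the bundled
analytic surface (3-fold torsional wells at the anti/gauche positions):

```r
library(torsconf)

zm  <- read_zmatrix(system.file("extdata", "butanol_chain.zmat",
                                package = "torsconf"))
pes <- toy_chain_pes(zm, rep(list(data.frame(amp = 1.4, mult = 3,
                                             phase = 0)), 3))
state <- conformer_search(zm, pes, has_sym_plane = TRUE,
                          batches = list(list(cycles = 50, d = 30)),
                          seed = 1)
print(state)
#> search_state: t=3 | K1=14 K1*=14 | K2=50 K2*=37 | J=14 (P=65)
efficiency_table(state)
#>   t K1 K1_star J1 K2 K2_star J2 J_LL
#> 1 3 14      14 14 50      37  0   14
```

The symmetry-reduced systematic pool holds 14 of the 3³ = 27 preconditioned
structures; all 14 optimize into distinct conformers (J₁ = 14), and 50
Monte Carlo cycles add nothing because on this model surface every well
sits on the preconditioned grid.  `expand_enantiomers(state)` regenerates
the mirror partners: 2·14 − 1 = 27 distinguishable structures (only the
all-anti conformer is its own mirror image).

```r
thermo <- thermo_from_search(state, lambda_zpe = 0.951)
thermo_table(thermo, c(300, 1000, 2500))[, 1:5]
#>      T   Q_MS_HO   Q_MS_QH    Q_MS_T ms_qh_over_1w
#> 1  300 1.822e+00 5.301e+00 5.301e+00         26.28
#> 2 1000 2.979e+09 5.748e+09 5.748e+09         26.95
#> 3 2500 1.139e+15 2.101e+15 2.101e+15         26.99
```

The MS-QH over one-well ratio climbs toward 27 — on this surface all 27
wells are isoenergetic, so the single-well approximation undercounts the
partition function by the full multiplicity.  `chi_populations()`,
`min_conformers_for_fraction()` and `ratio_report()` give the per-conformer
populations, the smallest conformer set recovering a target fraction of
the partition function (split by systematic/stochastic provenance), and
the MS-T(C) ratios.

A YAML-driven command line covers the same workflow
(`inst/cli/torsconf search --config run.yaml --seed 1`, plus
`systematic`, `stochastic`, `thermo` and `report` subcommands); every run
writes an efficiency table, a conformer table, an XYZ trajectory, a
plain-text log with one line per guess, a JSON checkpoint that resumes
bit-exactly, and a metadata record of all knobs.

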