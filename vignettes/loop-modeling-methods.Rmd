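---
title: "Hybrid-energy loop modeling by conformational space annealing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid-energy loop modeling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the structural model, the hybrid energy function and its parameters, the
closed-loop sampling and annealing machinery, the synthetic fixtures the
tests run on, and the numerical and design decisions taken where the
problem left them open.

## The modeling problem and the structural model

A loop is a contiguous segment (3–20 residues, 1-based inclusive range) of
one chain whose conformation is rebuilt while the remaining structure —
the *framework* or *environment* — stays fixed. The degrees of freedom are
the loop backbone torsions phi/psi/omega and the side-chain chi angles;
bond lengths and angles are held at ideal values during sampling
(internal-coordinate, or torsion-space, modeling). Structures are held in
a polar-hydrogen (united-atom) representation: hydrogens bound to N, O and
S are explicit, aliphatic and aromatic hydrogens are folded into their
carbon atom, which carries an enlarged van der Waals radius. The package
ships a reduced, self-contained parameter set (per-class radii,
Lennard-Jones well depths, SASA tensions, HCT descreening factors in
`inst/extdata/atom_classes.tsv`; per-atom partial charges and
internal-coordinate templates in the topology tables). These are idealized
textbook values assembled for this package, not a redistribution of any
force-field file; per-residue net charges are integral and the functional
forms, not the parameter provenance, carry the science under test.

Two conventions deserve emphasis because they define the interface between
the loop and the framework:

* **Peptide attachment atoms belong to the framework.** N(start) with its
  amide hydrogen, and the carbonyl C(end)/O(end), are never rebuilt. All
  closure targets derive from these fixed atoms plus the anchor-residue
  backbones (the position of CA(end) follows from sp2 planarity at the
  fixed carbonyl). This keeps the closure problem well-posed even when a
  framework carries no meaningful loop coordinates, and it makes psi(end)
  a determined quantity rather than a degree of freedom.
* **Chain breaks** are recorded where C(i)–N(i+1) exceeds 2.5 Å; loops may
  not span them. Cis-proline is flagged when omega is within 30° of zero,
  and sampling preserves the flag (omega is fixed at 180° otherwise).

Missing side-chain atoms in input structures are rebuilt from ideal
geometry at the most common rotamer; this is a documented divergence from
pipelines that import side chains verbatim.

## The hybrid energy

The total energy is the weighted sum

E_total = E_bonded + E_vdW + w_el (E_Coulomb + E_GB) + w_sa E_SA +
w_phipsi E_phi/psi + w_chi E_chi + w_hbond E_Hbond + w_atompair E_pair,

with defaults (0.16, 0.05, 1.2, 1.0, 4.0, 12.0) for
(w_el, w_sa, w_phipsi, w_chi, w_hbond, w_atompair). Terms are summed over
loop–loop and loop–environment interactions only; environment–environment
contributions are constant while the loop moves and are dropped. Terms
whose weight is zero are skipped entirely (and reported as zero), which
both preserves the composition identity exactly and lets reduced models
run fast.

Parameters that matter, with units and defaults:

* **Bonded**: harmonic bonds (k = 300 kcal/mol/Å²) and angles
  (k = 50 kcal/mol/rad²) with equilibrium values measured from the
  package's own ideal-geometry residue templates, plus 3-fold torsion
  barriers (0.3 kcal/mol) on rotatable chi bonds. In torsion-space
  sampling these terms are near zero by construction; their real role is
  to penalize junction strain in unclosed intermediates (see refinement)
  and to score arbitrary Cartesian input.
* **Lennard-Jones**: 12-6 with Rmin = r_i + r_j and geometric-mean well
  depths; 1-2/1-3 pairs excluded, 1-4 scaled by 0.5; switched off smoothly
  between 8 and 10 Å; repulsion continued linearly below 0.6·Rmin so that
  clashed starting points cannot produce unbounded forces.
* **Electrostatics**: Coulomb with the 332.06 kcal·Å/mol/e² prefactor and
  interior dielectric 1, same exclusions and switching; generalized-Born
  solvation with epsilon_solvent = 78.5 and Born radii from
  Hawkins–Cramer–Truhlar pairwise descreening (offset 0.09 Å, per-class
  scale factors). The descreening integral is implemented in closed form
  and is checked in the tests against numerical quadrature of the
  defining 1/r⁴ integral — the canonical two-sphere oracle.
* **Surface area**: Shrake–Rupley SASA with 192 deterministic
  Fibonacci-sphere points per atom and a 1.4 Å probe, times per-class
  surface tensions. The sphere-point orientation is anchored to a local
  frame built from two bonded neighbours, which makes the term *exactly*
  invariant under rigid transforms — a finite point set fixed in the
  laboratory frame would not be.
* **Backbone/side-chain statistics**: 36×36 grids (10° bins) of −ln
  relative density per residue class (general/glycine/proline, with
  sequence-dependent per-type grids honoured when present), bilinear
  periodic interpolation, RT = 0.5917 kcal/mol. Normalization invariant:
  exp(−value) averages to one over the torus, so a uniform table scores
  zero everywhere. Default tables are analytic Ramachandran-basin and
  rotamer-state mixtures built in code; `derive_torsion_tables()` replaces
  them with statistics from training structures.
* **Hydrogen bonds**: orientation-dependent wells over donor–acceptor
  pairs with at least one loop atom: a distance well centred at 1.95 Å
  (half-width 0.65 Å, so zero beyond 2.6 Å H···A), angular wells centred
  at 180° (donor) and 120° (acceptor). The angular terms are gated by the
  smooth distance envelope, which keeps the sum C¹-continuous — the tests
  scan for derivative jumps.
* **Atom-pair potential**: distance-binned (0.5 Å up to 15 Å) per
  class-pair table applied to heavy-atom pairs at sequence separation ≥ 2.
  `derive_pair_potential()` builds the table from counts against a
  distance-scaled ideal-gas reference, u = −RT ln[N(r) / ((r/r_c)^α
  N(r_c))], pseudocount 1, α = 1.61 by default; the last bin is the
  reference state and is exactly zero. The orientation-dependent extension
  of such potentials is out of scope here; the distance-only form is
  implemented.

Open compositional questions were resolved as follows: the weighted sum
above follows the linear composition with the electrostatics weight
multiplying Coulomb + GB jointly; the backbone-statistics term applies to
loop residues only, not to environment residues near the anchors.

## Closed-loop sampling

**Tri-axial loop closure.** Choosing three pivot residues splits the loop
into rigid legs. Because every rotatable axis at a pivot passes through its
C-alpha, the three C-alpha distances are conformation-independent and the
pivot triangle is rigid; each leg (and the anchor "virtual leg") then
rotates about a triangle edge by one azimuth. The three bond-angle
constraints at the pivot C-alphas become three cone–cone intersection
equations, biquadratic in the tangent half-angles. Eliminating two
variables by resultants (the inner resultant of two quadratics in closed
form, the outer one evaluated by the root-product formula with a Sylvester
determinant fallback) yields a degree-16 polynomial whose coefficients are
recovered exactly by evaluation on a complex circle and an FFT; real roots
come from companion-matrix eigenvalues, are polished by Newton iteration on
the exact trigonometric system to ~1e-12 residual, and are converted back
to pivot (phi, psi) pairs by placing the legs with exact three-point rigid
transforms. Solutions are returned sorted by total torsion change from the
input. Infeasible gaps (triangle inequality violated, or no real roots)
yield an empty list. Azimuth origins carry fixed offsets so that tangent
half-angle poles are not hit by generic problems. The test suite contains
an independent brute-force oracle — one-dimensional root scans of the cone
residuals themselves — and checks the solution sets agree root for root.

**FALC sampling.** Initial conformations draw (phi, psi) per position from
a fragment library derived from the same statistics table used by the
backbone-statistics energy (bins covering 98% of the probability mass by
default, uniform jitter within a bin), set omega to 180° (except flagged
cis-prolines), pick a uniformly random pivot triple with at least one
residue between pivots, and close analytically. Among closure roots the
one with fewest heavy-atom clashes (pair distance below 0.7 times the
radius sum, ties broken by least total torsion change) is kept; failed
closures are retried up to 50 times per sample. Side chains are placed at
the most common rotamer and then randomized over discrete rotamer states
with small Gaussian jitter. Everything is deterministic given the seed.

## Conformational space annealing

The bank of N closed conformations (defaults N = 30, M = 10 seeds for
loops under 12 residues; N = 50, M = 20 otherwise) evolves by iterating:

1. **Seed selection**: unused-first — members not yet used as seeds this
   cycle are preferred; when exhausted the flags reset.
2. **Crossover**: a contiguous torsion segment (length 2 to n/2) of a
   random partner replaces the seed's, and the splice is re-closed with
   pivots flanking the segment (least-change root). After repeated closure
   failure the move degrades to a single-torsion perturbation.
3. **Side-chain exchange**: up to 3 times, the full chi set of a random
   bank member is copied onto the trial and kept only if the total energy
   decreases. Environment side chains are not sampled (the protocol never
   samples beyond the loop region), so the exchanged chi sets are the
   loop's.
4. **Refinement**: a short noisy-descent phase followed by deterministic
   minimization in torsion space. The working gradient is the chain-rule
   projection of the Cartesian gradients of the smooth terms (bonded, LJ,
   Coulomb) onto the torsions, plus analytic derivatives of the
   interpolated statistics tables; GB/SA and the binned pair potential are
   held fixed during minimization (the fixed-solvation approximation).
   Steps are projected onto the tangent space of the closure constraint
   (the null space of the anchor Jacobian), so drift is second-order; the
   junction bond/angle terms restrain what drift remains, and the chain is
   re-closed analytically every few steps and at the end. Only closed
   states are candidates for the result, and the returned member never has
   higher energy than the input — the noisy phase can explore uphill, but
   the entry state is always retained as fallback.
5. **Bank update**: the member nearest to the candidate (unsuperposed loop
   main-chain RMSD — anchors are shared, so no superposition is the
   natural conformational metric) is found. Within D_cut the candidate may
   only replace that nearest member; otherwise it competes with the
   current worst. Replacement requires lower energy in either case, so the
   bank minimum is non-increasing by construction.

D_cut starts at half the initial mean pairwise bank distance and decays
geometrically to a fifth of it across the run (common annealing practice;
the controlling quantity is the ratio, not the absolute value). The run
stops after the configured iterations or after 5 iterations without any
replacement. Iteration count and trials per seed are configuration
(defaults 50 and 10); the desk-scale tests use much smaller values, stated
below. The bank energy minimum, rebuilt into the full structure, is the
final model.

## Synthetic fixtures and what they do (and do not) show

`make_scaffold()` builds ideal-geometry helix–loop–helix mini-proteins
(20–40 residues; the loop turn torsions were chosen once for compactness
and get small seed-controlled jitter), with side-chain rotamers relaxed by
a deterministic greedy clash-relief pass. `delete_loop()` replaces loop
coordinates by an uninformative extended rebuild while keeping the
framework-owned attachment atoms. `perturb_environment()` emulates the two
perturbed-framework benchmark regimes: side-chain mode rotates environment
chi angles continuously toward random rotamer states as the magnitude
crosses per-angle thresholds, backbone mode additionally applies AR(1)-
correlated Gaussian phi/psi noise to the whole framework (a dihedral-space
stand-in for thermal-ensemble relaxation — running molecular dynamics is
deliberately out of scope, and the emulation reproduces exactly the
measured axis, E-RMSD). The magnitude is bisected until the achieved
E-RMSD is within 0.15 Å of the target; the regime targets 0.9 Å
(side-chain) and 2.1 Å (backbone) are the benchmark regime means. Anchor
displacement is recorded; backbone mode may move anchors, side-chain mode
never does.

The planted-native fixture makes the recorded native loop the global
energy minimum by construction: per-residue-type phi/psi and chi tables
with multi-scale basins at the native values (a sharp 12° core for
discrimination, 30° and 90° shoulders so the gradient reaches across the
torus), steric repulsion softened (cap at 0.85·Rmin) and scaled down (vdw_scale =
0.05) so that the torsion tables determine the global minimum outright —
with full steric weight, compact decoys can trade torsion penalties
against relief of the scaffold's own packing noise — and
solvation/electrostatics off for speed. The sampling library is built from the same planted table,
concentrated on its top 25% probability mass. A planted fixture
demonstrates that the optimizer finds a known global minimum through the
full protocol; it does not demonstrate chemical accuracy of the default
energy on real proteins, which would require experimentally determined
test sets.

Because the scaffolds are small and ideal-geometry, passing tests show
correctness of the machinery (closure exactness, metric identities,
gradient consistency, bank-update semantics, parameter recovery), not
benchmark-level prediction accuracy; the published accuracy numbers for
this class of method depend on large curated PDB test sets and trained
tables that are outside this package's scope.

## Numerical choices and problem sizes

* Closure: 24-point circle for coefficient recovery; real roots kept when
  the imaginary part is below 1e-6 relative; duplicate roots merged at
  0.005° in azimuth space; Newton polish capped at 12 iterations.
* Refinement: step size adapts between 5e-2 and 4 (degrees per unit
  gradient), per-step displacement capped at 10°; re-closure every 5
  steps; shake noise 1.5° for 3 steps, then 10–12 descent steps by
  default. These defaults favour throughput; the minimizer fixed-point
  property is tested on an analytic quadratic landscape with a longer
  schedule (150 steps).
* The degenerate inputs — infeasible gaps, all-glycine chi lists,
  zero-weight terms, empty environments, loops crossing chain breaks —
  all have defined behaviour exercised by the tests.
* Desk-scale study sizes: the acceptance suite uses 8-residue loops on
  28-residue scaffolds for geometry/energy properties; the planted-native
  recovery runs 6-residue loops with N = 30, M = 10, 6 iterations and 2
  trials per seed over 10 seeds; the toy-landscape audit runs 4-residue
  loops over 20 seeds; pair-potential recovery uses 1e5 planted samples
  and a 10000-atom uniform gas (derived with the geometry-consistent
  exponent α = 2, since a finite uniform gas follows the r² law — the
  default α = 1.61 encodes the finite-size statistics of real proteins).

## Known limitations

* The pair potential is distance-only; the orientation-dependent
  refinement of such potentials is not implemented.
* GB radii use HCT pairwise descreening behind a swappable interface; no
  claim of numerical agreement with any specific published solvation
  parameterization is made, and GB/SA derivatives are neglected during
  minimization.
* Idealized ring geometry closes aromatic rings only approximately
  (closure error of a few thousandths of an Å), visible as a small floor
  in symmetric-flip RMSD identities.
* Proline is modelled with a fixed ring pucker and no chi sampling.
* Histidine is scored in a single neutral tautomer and excluded from the
  symmetric-flip set (its ring atoms are not two-fold symmetric in type).
* Environment side chains participate only through the fixed framework;
  extended sampling of the environment is deliberately not implemented.
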