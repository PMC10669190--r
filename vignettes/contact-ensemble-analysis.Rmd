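---
title: "Contact-based analysis of capped IDR peptide ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-based analysis of capped IDR peptide ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Intrinsically disordered regions (IDRs) such as the activation function 1
(AF1) region of the androgen receptor do not fold into a unique structure;
they are described by conformational ensembles. Covalent small-molecule
antagonists that ligate specific cysteines of AF1 (C406, C327) can shift
those ensembles — in particular, ligands carrying a cyanopyrazole B-ring
reduce the helical propensity of the 21-residue segment around C406, a
plausible step in neutralising AR condensates. Detecting such shifts
requires per-residue, per-frame statistics over thousands of conformations.

`contactdof` implements the full statistical toolchain for this kind of
study: residue–residue contact maps at an any-atom distance cutoff, the
"contact degree-of-freedom" (contact-DOF) representation of conformation,
eight-state secondary-structure assignment, fragment-resolved
protein–ligand contact profiles, and low-dimensional embeddings of contact
vectors. Because production molecular-dynamics trajectories are far beyond
desk scale, the package also ships a synthetic helix–coil ensemble
generator that plays the role of the sampler, with known ground truth.

## Segments, caps and indexing

A study system is a capped 21-mer centred on a cysteine: ten flanking
residues on each side plus ACE (acetyl) and NME (N-methylamide) caps
blocking the termini. Throughout the package, *internal indices* are
1-based and include the caps: the ACE cap is unit 1, so a 21-mer has 23
indexed units and the central Cys sits at internal index 12. For the 406
segment, W399 is residue #5 and A403 is residue #9:

```{r, eval = FALSE}
library(contactdof)
spec <- segment_spec(406)
internal_index(c(399, 403, 406), spec)
#> [1]  5  9 12
```

The packaged default sequences are *synthetic*: poly-alanine anchored at
the documented positions (Trp at 399, the central Cys). Only residue naming
and CB placement depend on sequence identity in the backbone-level model,
so none of the computed statistics are affected; users with real sequences
pass them to `segment_spec()` directly.

## The contact statistic

Residues j and k are in contact in a frame when *any* atom of j is within
4.2 Å of any atom of k. Choices pinned here:

* the boundary is inclusive (d ≤ 4.2 Å counts);
* hydrogens count like any other atom;
* sequence-adjacent pairs (|i−j| = 1, 2) are retained — the 23×23 map
  contributes exactly 23·22/2 = 253 non-redundant DOFs, which is only true
  if nothing but the diagonal is excluded;
* ligand atoms never count toward their host residue in residue–residue
  maps, keeping peptide-fold maps comparable between liganded and native
  systems.

The ensemble mean of per-frame binary maps is the contact heat map; the
row-major strict upper triangle of a map is its contact vector
(`vectorize_map()`), the coordinate system for all embeddings. The contact
kernel is validated in the test suite against a brute-force all-pairs
distance scan on every synthetic ensemble, and contacts are checked to be
monotone in the cutoff.

## Secondary structure

`assign_ss()` is a Kabsch–Sander style assignment: backbone hydrogen bonds
are detected with the classical electrostatic energy model
(E = 0.084 · 332 · (1/d~ON~ + 1/d~CH~ − 1/d~OH~ − 1/d~CN~) kcal/mol,
bond if E < −0.5), two consecutive n-turns define helices (n = 4 α, 3
3₁₀, 5 π), bridge patterns define strand states, with turn (T) and bend
(S, CA-trace kink > 70°) filling in; the priority on overlap is
H > E/B > G > I > T > S > none. Per-residue state fractions over frames are
the stacked-bar statistic; `helical_fraction()` sums the three helix
states.

Two conventions deserve note:

* **Caps.** ACE/NME participate as H-bond partners (ACE can accept, NME can
  donate) but receive no state themselves. This matches assignment run
  with caps present in the trajectory tooling this package emulates. The
  independent reference implementation used in the tests (mdtraj's DSSP)
  instead excludes caps entirely, so the two cap-adjacent residues
  (internal 2 and 22) can differ systematically — we may assign helix
  where the reference, blind to the cap, sees loop. The ≥ 95% agreement
  check in the tests is therefore computed over interior residues (3–21),
  where both implementations see identical inputs; measured agreement
  there is ≈ 99%, and all logged disagreements elsewhere are at the
  termini.
* **Amide hydrogens** are built by the generator; when reading external
  PDBs without them, positions are reconstructed geometrically (bisector
  convention) since the energy model requires H.

## The synthetic generator

`sample_helix_coil()` stands in for MD sampling of the helix–coil
transition. Each frame draws a per-residue helix/coil state vector from a
two-state Markov chain along the sequence with marginal helical
probability `p_helix` and nearest-neighbour persistence `rho`
(`P(s_i = 1 | s_{i−1} = 1) = p + ρ(1−p)`, `P(s_i = 1 | s_{i−1} = 0) =
p(1−ρ)`), so the marginal is exactly `p` while helical residues occur in
cooperative runs of mean length `1/((1−p)(1−ρ))`. Helical residues are
built at ideal α dihedrals (φ = −57°, ψ = −47°); coil residues draw
dihedrals uniformly from two rectangular Ramachandran basins (a β/PPII
box and a broad extended box), both avoiding the α region so that coil
residues break i,i+4 hydrogen bonding. Frames are constructed by an
idealised backbone builder (textbook internal geometry, trans ω; backbone
plus amide H, carbonyl O, one CB pseudo-atom per non-Gly residue, SG on
Cys) — enough side-chain reach for realistic contact statistics without
rotamer modelling.

Defaults, fixed package-wide:

| parameter | default | meaning |
|---|---|---|
| `p_helix` | 0.85 | marginal helical probability (helix-stable systems) |
| `rho` | 0.9 | nearest-neighbour persistence; mean runs ≈ 10–15 residues |
| cutoff | 4.2 Å | any-atom contact threshold |
| stride | 1 frame | stored frames are already on the 10 ps analysis grid |
| blocks | 2 | first/second-half convergence blocks ("_1", "_2") |

`rho = 0.9` reflects strong helix–coil cooperativity: short peptides
nucleate rarely and extend readily, so helical content arrives in long
runs, as transient helical segments do in disordered regions. A
consequence worth understanding is that cooperativity broadens the
*per-frame* helix-content distribution: at `p = 0.3` individual frames
range from fully coil to largely helical. Mean per-residue statistics
(state fractions, mean contact maps) recover `p` accurately, but single
frames of a `p = 0.3` and a `p = 0.9` ensemble genuinely overlap in
conformation space, so no frame-level 1-D projection can separate such
ensembles nearly perfectly. Separation to a few percent is obtained for
clearly helix- vs coil-dominated ensembles (e.g. `p = 0.95` vs
`p = 0.05`). We deliberately kept the physically motivated `rho` rather
than weakening cooperativity to sharpen frame-level separability: lower
`rho` shortens helical runs below the 4–5 residues a hydrogen-bond
pattern assignment needs, degrading helicity recovery at moderate `p`.

### The pseudo-ligand

`attach_pseudo_ligand()` bonds a coarse dual-ring ligand to the central
Cys sulfur: a three-atom stem (linker) and five-atom A-ring and B-ring
groups, each atom carrying exactly one fragment label. Ring chemistry is
*not* modelled atom-for-atom, and the ligand has no chirality. Without
bias the ligand points away from the peptide; with
`bias = list(target = r, fraction = f)` the B-ring is placed in contact
range of residue r's CA in a Bernoulli-f subset of frames (and held clear
of r in the rest), treating the linker as freely flexible. The
fragment-resolved contact profile — % of frames with any fragment atom
within the cutoff of each residue — then shows the designed signature: a
maximum at the target residue at ≈ 100·f %, near zero at distal residues.

What the generator emulates: cooperative helix–coil statistics, cap
bookkeeping, fragment-labelled ligand contacts with tunable specificity,
seeded reproducibility. What it does not: force-field energetics, solvent,
kinetics/time correlation, side-chain packing, β-sheet formation, and real
ligand chemistry. Tests passing on synthetic data validate the
*statistics pipeline*, not any claim about real AR trajectories.

### Scenario defaults

`run_system()` maps registry systems to generator settings
(`scenario_defaults()`): unliganded systems sample `p = 0.85`; systems
with a destabilising B-ring (XNN, XN0) sample `p = 0.45` with B-ring bias
0.6 at residue #5; weak binders (XNB, XEN) sample `p = 0.80` with a weak
(0.15) bias elsewhere. These emulate the qualitative study conditions —
helix retention for native/XNB, destabilisation plus W399-adjacent B-ring
contacts for XNN/XN0 — and are deliberately simple: the liganded ensemble
is not coupled frame-by-frame to ligand position.

## Embeddings

`pca_embed()` performs mean-centred *covariance* PCA of contact vectors
(no correlation scaling: all DOFs share the 0/1 scale; binary DOFs with
zero variance would also make correlation scaling ill-defined). Component
signs follow a fixed convention — the largest-magnitude loading is
positive — so projections are deterministic. Invariants checked on every
run of the test suite: orthonormal loadings, non-increasing explained
variance, eigenvalue sum equal to total centred variance, and agreement
with a brute-force covariance eigendecomposition on small instances.

`nonlinear_embed()` provides the nonlinear conformation projection. The
backend is non-metric multidimensional scaling (vegan's `monoMDS`) on
Euclidean contact-vector distances, with classical metric scaling
(`cmdscale`) as an alternative; both are established manifold projections
that preserve global dissimilarity structure, are seeded-deterministic,
and record their parameters in the result. Degenerate input (all vectors
identical) returns coincident coordinates with a warning rather than an
error.

`joint_embed()` fits one embedding on the pooled frames of several
ensembles and returns labelled per-system projections. Note the inherent
instability this implies: projections change when the pool changes, so
per-block and pooled projections of the same system differ — a property
of collective-coordinate analysis, not a bug.

## Numerical choices and degenerate inputs

* Contact boundary inclusive, with a 10⁻¹² slack on squared distances
  against floating-point ties.
* Block splitting gives earlier blocks the remainder (101 → 51 + 50).
* PCA of identical vectors yields zero variance and zero projections.
* `unvectorize_map()` restores the diagonal to 1 (the conventional value,
  excluded from DOFs).
* H-bond distances below 0.5 Å are clamped in the energy model.
* The builder errors on dihedrals outside (−180°, 180°] and on
  residue-count mismatches; built dihedrals reproduce requests within 1°.
* Seeds: the generator seed fixes states and coil dihedrals; the ligand
  placement uses an offset seed; pipeline systems derive per-system seeds
  from the master seed and notation (kept below 2³¹).

## Problem sizes

The test suite runs ensembles of 10–500 frames for unit checks, 2000
frames for convergence checks (binomial error on a state frequency at
n = 2000 is ≈ 0.01, so ±0.03 bounds are comfortable), and 30-frame
ensembles for the reference DSSP comparison. These sizes are the
package's own choices for tight, informative checks at interactive
runtimes.

## Known limitations

* Single chain only: no inter-chain contacts or bridges, so the strand
  states E/B rarely occur in synthetic data and are exercised mainly
  through the reference comparison.
* The DSSP variant is the classic Kabsch–Sander rule set; tool-specific
  variants differ at pattern boundaries, which the reference-comparison
  tolerance absorbs.
* The pseudo-ligand's flexible-linker placement can stretch bonds between
  the stem and a strongly biased B-ring; fragment contact statistics are
  unaffected, but the ligand geometry is not a chemical model.
* No solvent, energies, or kinetics anywhere.
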