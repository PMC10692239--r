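---
title: "Assembling multi-domain proteins from inter-residue affine transforms"
author: "domasm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling multi-domain proteins from inter-residue affine transforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domasm)
```

## The problem

Many proteins fold into several compact domains joined by short flexible
linkers. Individual domains are often known or predicted accurately, while
the *relative placement* of domains — governed by a handful of linker
torsions — is not. `domasm` treats assembly as an optimization problem:
given rigid single-domain structures, a domain layout, and a set of
predicted (or structure-derived) inter-domain residue–residue
interactions, find linker conformations (and, for complexes, chain
placements) whose implied inter-domain geometry best satisfies the
interactions.

## Inter-domain interactions as 6D affine transforms

Every residue carries a local orthonormal frame built from its backbone
N, Cα and C atoms by Gram–Schmidt: origin at Cα, x-axis along Cα→C,
y-axis the component of Cα→N orthogonal to x, z = x × y. For an ordered
inter-domain residue pair (i, j), the relative transform
A(i,j) = A(i)⁻¹ ∘ A(j) maps residue-j local coordinates into residue i's
frame. It is encoded as a 6-vector:

* (α, β, γ): intrinsic ZYX Euler angles of the rotation,
  R = Rz(γ)·Ry(β)·Rx(α);
* (r, θ, φ): spherical coordinates of the translation,
  t = (r sinθ cosφ, r sinθ sinφ, r cosθ).

Because frame origins sit on Cα, `r` is exactly the Cα(i)–Cα(j)
distance. The codec is bijective away from the Euler degeneracy at
β = ±90°; at gimbal lock the convention α := 0 is used and the residual
rotation absorbed into γ, so the rotation (though not the angle triple)
is always reconstructed exactly.

A learned predictor emits *binned* distributions over each element. The
package's structure-derived oracle (`oracle_interactions()`) stands in
for such a predictor offline: it emits the exact transforms of a
reference structure for all ordered inter-domain pairs with Cα–Cα
distance ≤ `r_max` (both (i, j) and (j, i)). `discretize_targets()`
converts exact targets into binned distributions (optionally blurred by
a discretized, periodic-wrapped Gaussian), and `decode_distributions()`
reverses this by taking each element's arg-max bin midpoint, dropping
pairs whose distance lands in the "no interaction" overflow bin.

### Bin scheme

The published featurization states that the six elements are binned and
one-hot encoded but not the bin geometry, so the scheme here is a
package choice, recorded in every interaction file header so energies
are reproducible:

| element | range | width |
|---|---|---|
| r | [2, 40] Å + overflow | 1 Å |
| α, γ, φ | [−180°, 180°) | 15° |
| β | [−90°, 90°] | 15° |
| θ | [0°, 180°] | 15° |

Midpoint decoding therefore quantizes each element by at most half a
bin. Propagated through the energy, the azimuthal and polar half-bins
(7.5° ≈ 0.13 rad) dominate at large `r`: on the bundled fixtures a
zero-blur decoded map scores its own target at ≈ 2–4 Å ACD rather than
zero, and the decoded distance error is ≈ 0.25 Å (half the 1 Å bin on
average). These are the quantization floors the tests assert.

## The atomic coordinate deviation (ACD) energy

Scoring a conformation against targeted transforms uses

F_ACD = (1 / N_tot) Σ over ordered pairs (i,j) and atoms k ∈ {N, Cα, C, Cβ}
of ‖ A(i)⁻¹ ∘ x(j,k) − A(i,j) ∘ A(j)⁻¹ ∘ x(j,k) ‖₂

where A(i), A(j) are the conformation's current frames, x(j,k) the
ground-frame position of atom k of residue j, and A(i,j) the targeted
relative transform; N_tot = 4 × (number of ordered pairs). The energy is
zero exactly when every targeted transform is realized, is invariant
under any global rigid motion of the conformation (every term lives in a
local frame), and is unchanged when pairs are duplicated (mean
normalization). No per-term clamp is applied by default — the definition
is taken literally — though `acd_context(clamp =)` provides one for
robustness experiments, and an optional soft steric term
(`steric_weight`, default 0, penalizing inter-domain Cα pairs closer
than 3.6 Å) is available as an extension; both are excluded from all
shipped checks.

Glycine has no Cβ; to keep the atom set uniform, every residue lacking a
stored Cβ receives an ideal virtual one (1.522 Å from Cα, tetrahedral
L-configuration placed in the local frame), so S_atoms is identical
across residues. `pacd()`/`tacd()` evaluate the same functional against
a predicted map and against a reference structure's oracle,
respectively; comparing them measures how faithful a predictor's
interactions are.

## Kinematics

Domains are rigid bodies. The decision variables are φ/ψ offsets of the
movable linker residues around each domain boundary — by default 8
residues per boundary, split 4 + 4 across the junction — plus one rigid
6-DoF slot (rotation vector + translation) per non-anchor chain.
`apply_torsions()` processes offsets N→C: a φ offset rotates the
residue's own C/O/Cβ and all later residues of the chain about the
N–Cα axis; a ψ offset rotates the residue's O and all later residues
about Cα–C. The axis sign is chosen so a positive offset *adds* to the
conventional dihedral. This preserves all bond lengths and angles
exactly, makes the zero vector an exact identity, and makes offsets
compose additively (they are internal coordinates).

One consequence of the 4 + 4 window is that the outermost residues of
each domain are movable: strict rigidity holds for the *core* of each
domain (its residues outside the movable windows), and that is the
invariant the tests assert. Chain-slot rotations act about the chain's
current Cα centroid; with the rotation-vector parametrization, negating
a slot's genes exactly undoes its move.

`initial_full_length()` concatenates domains with ideal peptide
junctions (C–N 1.329 Å, ω = 180°, ideal angles; the incoming domain is
superposed onto NeRF-placed junction atoms) and then randomizes the
movable torsions uniformly on [−π, π); non-anchor chains are placed with
a uniform random orientation and a centroid drawn inside the anchor's
bounding sphere inflated by 30 Å.

## Population-based assembly

The optimizer follows the published protocol: a pool of `pool_size`
(default 1,000) random full-length models is evolved for `iterations`
(default 500) steps; at each step every parent produces one offspring by
uniform crossover with a uniformly chosen distinct mate followed by
per-gene mutation, and the slot keeps whichever of parent and offspring
has the lower ACD energy. This pairwise elitism makes the best pool
energy non-increasing by construction. The `top_k` (default 10) models,
ranked by energy, are returned.

Operator constants are engine choices. Mutation is a *multi-scale*
wrapped Gaussian: each perturbed gene draws its width as
`mutation_sd · 10^u` with u ~ U(−3, 0) and a nominal `mutation_sd` of
120° (2 Å nominal for slot translations). The wide nominal scale lets
the population keep hopping between torsion basins late in a run — the
ACD landscape in linker-torsion space is multimodal, and a narrow fixed
width (e.g. 30°) strands the pool in the first basin it finds — while
the 10⁻³ tail supplies fractional-degree refinement moves from the same
constant. Crossover rate 0.5 and mutation rate 0.1 per gene are
conventional and were kept.

### Local refinement stage

A production pipeline would hand the coarse-grained pool winners to a
full-atom refinement protocol; that stage is out of scope here, and a
derivative-free torsion-space analogue under the *same* ACD objective is
run instead (`refine = TRUE` by default). It is a deterministic
multi-start cyclic block descent over the incumbent and the neutral
(zero-offset) vector: for each boundary block, a coarse 30° grid over
the two junction-flanking torsions (ψ before, φ after the junction)
followed by Nelder–Mead on the whole 16-gene block; for each chain slot,
Nelder–Mead from the current pose plus three seeded random
re-orientations; finally a joint Nelder–Mead polish. The refined vector
replaces the incumbent only if its energy is lower, so the evolutionary
trace's monotonicity and the run's bit-reproducibility are unaffected.
The neutral start matters when domains are carved from a longer
structure (linker geometry inside each domain is then already correct
and only the junction needs searching) — the same situation as
assembling experimentally determined domains. Analytic gradients are
deliberately not used anywhere; the optimizer is derivative-free
throughout.

### Determinism

All stochastic stages draw from per-stage seeds derived from `rng_seed`
by fixed offsets (initial individuals i use `seed + 100003·(i+1)`; the
evolution/refinement stream uses the offset at i = −1), so runs are
bit-identical for any pool size and reproducible from the run-manifest
JSON alone.

## Synthetic fixtures

`make_ideal_domain()` builds poly-alanine backbones from ideal internal
coordinates (helix φ = −57°, ψ = −47°; strand φ = −120°, ψ = +120°;
ω = 180°; bond lengths/angles N–Cα 1.458, Cα–C 1.525, C–N 1.329 Å,
N–Cα–C 111.2°, Cα–C–N 116.2°, C–N–Cα 121.7°) by sequential placement.
`make_multidomain_target()` joins domains through linkers with
seed-fixed random torsions, redrawing until the target is clash-free
(minimum inter-domain Cα–Cα ≥ 3.5 Å); linker residues are assigned half
to each flanking domain so the default movable window brackets the
junction. The standard suite (`fixture_suite()`) contains a two-domain
helix pair (68 residues), a three-domain helix/strand/mixed chain
(84 residues), and a two-chain pseudo-complex (2 × 30 residues).

These toys emulate the geometry of the assembly problem — rigid domains,
flexible linkers, exact ground truth — but not real data: there is no
sequence diversity, no side chains beyond the ideal Cβ, no missing
residues or experimental noise, and oracle interactions are exact where
a learned predictor's are not. Passing the recovery tests therefore
demonstrates that the representation, potential and optimizer are
internally consistent and can invert the oracle; it says nothing about
prediction accuracy on real proteins, which depends entirely on the
quality of the supplied interaction maps.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run the recovery experiment at
pool 128 / 300 iterations (seeded), which on the fixture suite yields
sub-0.2 Å Cα RMSD reconstructions from exact oracle maps and ≈ 0.1 Å
from blurred, arg-max-decoded maps; codec and energy checks use 10,000
random transforms and 100 random small energy instances against
independent brute-force oracles. The package defaults
(1,000 / 500 / top-10 / 8 linker residues) mirror the published
protocol and are what `assembly_config()` and the CLI resolve without
flags.

## Known limitations

* Domain layouts are inputs; no boundary prediction is attempted.
* mmCIF, insertion codes, altloc beyond blank/'A', and multi-model
  ensembles are not parsed; side chains beyond Cβ are ignored.
* The TM-score search is the standard fragment-seeded iterative
  heuristic; as a heuristic maximization it can slightly under-attain
  the true optimum on adversarial inputs.
* Inter-chain junctions are rigid 6-DoF slots, not covalent
  pseudo-linkers; the group-action additivity that holds exactly for
  torsion genes is only approximate for slot rotations.
* Energy ranking is by ACD alone; no model-quality assessment or
  full-atom refinement is performed.
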