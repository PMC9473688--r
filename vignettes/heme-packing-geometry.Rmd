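---
title: "Methods: heme packing geometry in cytochrome nanowires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heme packing geometry in cytochrome nanowires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemewire)
library(dplyr)
```

`hemewire` quantifies how heme cofactors pack inside multiheme cytochromes
and cytochrome filaments. This vignette is the package's account of the
underlying methods: the statistics it computes, the parameters that matter
and their defaults, what the synthetic generator does and does not
emulate, and the numerical and design choices that were genuinely open.

## The porphyrin ring and why 25 atoms

Every heme (covalently bound *c*-type `HEC` or non-covalent *b*-type
`HEM`) shares a porphyrin core of 25 non-hydrogen atoms: the iron, four
pyrrole nitrogens (NA–ND), sixteen pyrrole carbons (C1A–C4D) and four
methine bridge carbons (CHA–CHD). Vinyl and propionate substituents differ
chemically between heme types and are flexible, so all *geometry*
statistics use only the core; this is the only 25-count non-hydrogen set
consistent with standard HEC/HEM nomenclature. A heme missing any core
atom is excluded from geometric analysis (with a warning) rather than
imputed: mixing measured and invented atoms would contaminate distance and
angle statistics. Solvent-exposure calculations, by contrast, sum over
*all* atoms of the heme residue, because exposure of the substituents is
physically real; `shrake_rupley()`'s per-heme table makes this choice
explicit.

## Pair geometry

Two statistics summarise a heme pair:

- **Minimum ring distance** ("edge-to-edge"): the minimum over all
  25 × 25 atom–atom distances, regardless of atom type. It is symmetric
  and agrees exactly with a brute-force double loop (tested). Pairs at
  ≤ 6 Å count as contacts — close enough for efficient electron tunnelling
  between cofactors. Whether such a filter should include the propionate
  arms is ambiguous in practice; this package deliberately uses ring atoms
  only, so contact sets may differ at the margin from analyses that use
  whole ligands.
- **Rotation angle θ**: rings are superposed by least-squares rigid
  fitting (Kabsch SVD, proper rotations only) with correspondence *by
  canonical atom name*. The rotation matrix's angle,
  θ = arccos((tr R − 1)/2) ∈ [0°, 180°], measures relative orientation:
  0° parallel, 180° antiparallel (flipped). Name-based correspondence is
  essential — the pyrrole rings A–D are chemically distinct, and matching
  them by name breaks the ring's geometric four-fold pseudo-symmetry that
  would otherwise make θ multivalued.

θ is invariant under any common rigid transform and symmetric in the pair
(the angle of R equals that of Rᵀ); both properties are asserted as tests.

**Motif classes.** Packing surveys show orientation clusters rather than
sharp classes, so the discretization is a package choice: `parallel` for
θ < 40°, `antiparallel` for θ > 140°, `T_shaped` when the ring-*plane*
angle is in [60°, 120°], otherwise `intermediate`. θ alone cannot decide
T-shapedness — a quarter-turn about the ring normal gives θ = 90° with
coplanar rings — so `classify_motif(theta, plane_angle)` takes the plane
angle as a second argument, defaulting to `theta` (exact for pure tilts
about an in-plane axis). The unusual tight pairs worth flagging are those
with θ between 50° and 90° at distances below 5 Å
(`rare_pair_flags()`): in survey data that orientation band normally
occurs at 6 Å or more.

**Pruned best-subset superposition.** To compare globally dissimilar
structures that share a conserved core, `pruned_superposition()`
iteratively drops correspondences whose residual exceeds
`prune_factor × RMSD` (default 2.0) and refits until stable or fewer than
four pairs would remain. The factor 2.0 is a package default; published
"best aligned N atom pairs" numbers rarely state their pruning rule, so
matching a specific published subset should not be expected.

## Chain topology

Contacts define an undirected heme graph (parallel edges collapsed to the
smallest distance). The **main chain** is defined as the longest simple
path in the largest connected component — filament heme chains are nearly
linear, so this is found exhaustively for components of up to 24 hemes
(cheap at the one-to-three-subunit scale the package targets) and by a
double-sweep diameter heuristic above that. Ties break deterministically
by (chain id, residue number). Hemes off the main chain are **branches**,
reported with their attachment heme(s); the biologically interesting case
is a degree-1 pendant heme, which gains solvent exposure precisely because
it leaves the packed chain. "Main chain" has no universal algorithmic
definition in the literature; longest-simple-path is this package's
formalization and reproduces the intuitive tracing on linear and branched
fixtures, but a cyclic or mesh-like contact graph would make it ambiguous
(a warning is raised when no simple path covers half the component).

## Solvent accessibility

`shrake_rupley()` implements sphere-point counting: each atom's van der
Waals sphere is inflated by the probe radius (default 1.4 Å, a water
molecule), a deterministic golden-spiral lattice of `n_sphere_points`
(default 960) test points is placed on it, and the accessible fraction is
the fraction of points outside every neighbouring inflated sphere. Radii:
C 1.70, N 1.55, O 1.52, S 1.80, Fe 1.80 Å, anything else 1.70 Å. The
lattice is deterministic, so results are exactly reproducible; accuracy is
tested three ways (analytic isolated sphere, analytic two-sphere caps,
Monte-Carlo rejection sampling) and the lattice converges to well under
0.5% on doubling the point count. Buried interface area follows the
per-side convention (SASA_A + SASA_B − SASA_AB)/2, with `per_side = FALSE`
giving the total; published "interfacial buried area" values do not always
say which convention they use, so both are exposed.

Published per-heme exposure values for specific deposited models depend on
unstated algorithm parameters (probe, point density, and especially the
*context* — monomer versus filament). The package's convention is to state
context explicitly: `heme_sasa(atoms, chain, seq, context_chains = ...)`,
with the recommendation that filament heme exposure be computed with both
flanking subunits present.

## Helical symmetry

A 1-start helical filament is described by rise (Å per subunit) and signed
twist (degrees per subunit); the axis is fixed to z by convention and
deposited models are used as-is, without re-alignment. Derived quantities:
pitch = rise × 360/|twist| (handedness-invariant), meridional layer line
at 1/rise, 1-start layer line at 1/pitch. `expand_filament()` applies the
exact screw operation (rotation about z by i·twist, translation i·rise)
and warns on inter-copy clashes below 1 Å. For the parameters used
throughout the examples — rise 58.1 Å, twist −158.2° — the pitch is
`r round(pitch(helical_params(58.1, -158.2)), 1)` Å.

## The synthetic generator: what it does and does not emulate

`make_pair()` and `make_filament()` exist so that every analysis step can
be checked against exact ground truth without any external coordinates.

- The **ideal porphyrin** is planar with exact geometric C4 symmetry
  (Fe–N 2.00 Å). Because quarter-turns and in-plane flips map the atom set
  onto itself, stacked rings realize designed spacings *exactly*, which is
  what makes 1e-6-level round-trip tests meaningful rather than
  tolerance-limited.
- `make_pair()` rotates a second ring by a designed θ about a chosen axis
  and solves the translation by root finding (tolerance 1e-12 Å) so the
  achieved minimum distance equals the target.
- `make_filament()` stacks the chain hemes of each subunit along the
  helical axis at `chain_spacing` (default 4.5 Å, the middle of the
  3.6–5.7 Å range typical of packed filament chains), alternating in-plane
  flips (θ = 180°) with quarter-turns (θ = 90°); designated positions
  become pendant branch hemes placed laterally at a designed contact
  distance (default heme 6 at 4.6 Å off heme 5, the branched-octaheme
  architecture). Subunits are replicated by the rise/twist screw with the
  interface gap solved so terminal hemes of adjacent subunits meet at
  `interface_pair_distance` (default 4.5 Å), which with twist −158.2°
  makes the interface pair antiparallel.

Two deliberate simplifications. First, a straight-axis toy chain cannot
honour an arbitrary rise *and* a designed interface contact
simultaneously (real subunits fold their heme chain; the toy stacks it),
so the generator derives the rise from the chain extent plus the solved
interface gap and records it in the ground truth; passing `rise` overrides
the solve. Second, the alternating orientations use a quarter-turn about
the ring normal rather than a true perpendicular-plane T-contact, because
a perpendicular ring at 4.5 Å spacing on a straight axis would clash with
its chain neighbours; pair distances, θ values and topology are unaffected,
but the quarter-turn pairs classify as `intermediate`, not `T_shaped`.

More broadly, the synthetic hemes carry only the 25 core atoms, no protein
scaffold, no substituents, no ruffling or doming, and no coordinate noise.
Passing round-trip tests therefore demonstrates the correctness of the
*analysis chain* — it says nothing about model quality, map resolution or
conformational heterogeneity in real structures. Surface-area fixtures are
separate random atom clusters with analytic and Monte-Carlo references,
since ring-only hemes have unrealistically large exposures.

## Numerical choices

- Rotation angles are evaluated as atan2(|sin θ|, cos θ) from the
  antisymmetric part and half-trace of R — identical to
  arccos((tr R − 1)/2) but stable at 0°/180°, where the bare arccosine
  loses half the working precision; the cosine is clamped into [−1, 1].
- Kabsch superposition enforces det R = +1 via the sign of det(VUᵀ)
  (no reflections). The test suite cross-checks RMSDs against an
  independent quaternion (Horn) implementation.
- Root finding for designed distances uses `uniroot` at 1e-12 tolerance
  on translation magnitude; minimum-distance functions are continuous and
  monotone along the solved direction.
- Alternate conformers: highest occupancy wins, ties toward altloc "A",
  then alphabetical — a package choice, since survey-scale analyses rarely
  state their altloc handling.
- Degenerate inputs: self-pairs error; non-rotation matrices error at
  1e-6 orthonormality/determinant tolerance; empty structures error for
  SASA and PDB output; heme-free structures yield empty (not failing)
  results in `extract_hemes()` and `survey()`.

## Problem sizes

The test fixtures use one- to three-subunit filaments of 5–8 hemes per
subunit (up to 600 atoms), 10-atom clusters for Monte-Carlo SASA
validation (10⁶ samples per atom), and 10-structure corpora for the
survey; these sizes exercise every code path, including the exhaustive
longest-path search at its 24-node design limit, while keeping the whole
suite fast on a single CPU.

## Known limitations

- SASA is O(N²) in atoms with a dense neighbour matrix; it is designed for
  single filaments or complexes (thousands of atoms), not whole-PDB
  sweeps.
- Exposure and buried-area comparisons against published values are
  tolerance-based, not exact, because published SASA parameters are
  usually unstated.
- The contact survey treats the first model of multi-model files only and
  never forms cross-structure pairs.
- No electrostatics, no electron-transfer rate theory, no reduction
  potentials: the package measures geometry, which constrains but does not
  determine conduction.
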