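---
title: "Grid-based contact geometry: model, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based contact geometry: model, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactvol)
```

## The model

Every heavy atom of a structure is a hard sphere with a van der Waals
(vdW) radius; for contact analysis the sphere is expanded by a solvent
probe radius (1.4 Å by default), the radius of a water oxygen.  Two atoms
are in contact when their expanded spheres overlap, and `contactvol`
quantifies that overlap three ways:

* **Contact area** `S`: the part of one atom's expanded surface lying
  inside the partner's sphere.  The surface is discretized into `n`
  near-uniform points (5000 by default), each representing
  `Δs = 4πr²/n`; a surface point covered by `ci` atoms besides its host
  contributes `Δs/ci`, so surface shared among several contacts is
  counted once per host traversal.  The reported pair area is the mean of
  the two one-sided areas, because spheres of different curvature expose
  different areas in the same overlap region.
* **Contact volume** `V`: the lens-shaped overlap volume, estimated on a
  cubic lattice (0.2 Å spacing by default, volume element
  `Δv = spacing³`) anchored at each atom's center.  A lattice point of
  the host lying inside the partner contributes `Δv/ci`, where `ci`
  counts all other atoms covering that point — crowded regions are
  shared, never double counted.  The pair value is the mean of the two
  one-sided lattice sums, which makes `V(a,b)` and `V(b,a)` bit-identical
  and halves the discretization bias.
* **Atomic-overlap-weighted volume** `V0` (AOWV): the same lattice
  traversal weighted by the total occupancy `1 + ci` instead of shared.
  On an isolated pair every point has `ci = 1`, so `V0 = 2V` exactly;
  deeper overlap pushes `V0` above that bound.  AOWV emphasizes regions
  where many atomic clouds interpenetrate, a proxy for the space
  available to shared electron density.

Per-atom solvent-accessible surface area (SASA) falls out of the same
surface scan: `Δs` times the number of surface points inside no other
expanded sphere.  On a two-atom system the exposed and buried points
partition the surface point set exactly, a closure the test suite asserts
to machine precision.

## Water-mediated contacts and mosaic distances

Not every protein atom interacts with water, so a uniform 1.4 Å solvent
expansion overstates hydrophobic contacts.  The water-mediated mode
(`-p`) restricts scoring to pairs carrying at least one hydrophilic atom
(N, O, P or S) whose vdW-sphere gap is below one water diameter (2.8 Å),
and scores the pair through a virtual bridge water of radius 1.4 Å
rather than through direct sphere overlap.

How deeply a water may interpenetrate a protein atom's vdW sphere — the
*mosaic distance* — is element-specific: at most 0.1 Å for nitrogen,
0.2 Å for oxygen, 0.3 Å for phosphorus and 0.5 Å for sulfur.  The bridge
water is placed on the inter-atomic axis at `r_vdW + 1.4 − m` from its
anchor, where `m` is the anchor element's mosaic maximum.  When the
partner's sphere leaves no room, the water is pushed *away* from the
anchor (never deeper into it), so the achieved mosaic distance never
exceeds the table maximum, and the scored overlap shrinks monotonically
as the gap widens — reaching zero at the 2.8 Å eligibility limit.  With
two hydrophilic atoms each gets its own anchored water and the pair
score is the mean of the two atom-water contacts; the standalone shared
placement operation instead returns the on-axis point minimizing the
larger of the two mosaic-target violations (both met exactly when the
gap equals `2.8 − m_a − m_b`).

The eligibility criterion deliberately uses the *gap between vdW
spheres*, not the center distance: a 2.8 Å center-distance criterion
would exclude nearly every non-bonded heavy-atom pair, since two carbons
alone span 3.4 Å of vdW radius.

## Contact classification

Peptide bonds (backbone C(i)–N(i+1), same chain, ≤ 1.6 Å) and disulfide
bridges (CYS SG–SG within 1.95–2.1 Å) are covalent and are excluded from
non-covalent typing.  Non-covalent labels can co-occur and are reported
as a set with a fixed priority for single-label columns
(Cova > HB > AROM > PHOB > DC > OTHER): hydrogen bonds are
donor/acceptor pairs within 1.5–3.5 Å; AROM joins two aromatic-ring
atoms, with the histidine aromatic set restricted to the three imidazole
carbons CG, CD2 and CE1; PHOB joins two carbons; DC (destabilizing
contact) joins a carbon with a hydrophilic atom.  Residue pairs carry a
sequence-separation class — S (1–2), M (3–4), L1–L6 (5–10 through >50)
within a chain, I across chains.

Backbone φ/ψ dihedrals use the standard IUPAC torsion convention in
(−180°, 180°], reported only for standard amino acids whose backbone is
complete and peptide-bonded to its neighbor; anything else serializes as
an empty field rather than a guess.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| surface points | 5000 (15092 enhanced) | per-atom surface discretization |
| lattice spacing | 0.2 Å (0.1 enhanced) | cubic volume grid |
| solvent radius | 1.4 Å | probe expansion (water oxygen) |
| eligibility gap | 2.8 Å | water-mediated mode; `-d` overrides |
| area/volume cutoffs | 0, 0 | `-c`; 0.5 Å² / 0.25 Å³ suggested for NMR ensembles |
| flexibility thresholds | mean ≥ 30 Å³, range ≥ 100 Å³ | `flag_flexible_contacts()` |

The vdW radii are the Bondi element set, bundled as a versioned CSV;
per-(residue, atom) entries resolve through a standard-residue heavy-atom
dictionary and anything else falls back to the element radius with a
`guessed` flag.  Because published tools differ in their radius tables,
absolute areas and volumes carry a radius-dependent offset relative to
tools built on other tables; all internal comparisons are unaffected.

## Numerical choices

* **Surface construction.**  Spherical Fibonacci (golden-angle) lattice:
  deterministic at any point count, near-uniform (nearest-neighbor
  spacing spread below 2×), no randomness anywhere in the engine.
* **Lattice anchoring.**  Each atom's volume lattice is anchored at its
  own center, making per-atom results translation invariant.
* **Boundary guard.**  Sphere membership is tested as
  `d² ≤ r²(1 + 1e-9)`.  Without the guard, configurations whose overlap
  boundary passes exactly through lattice points (integer-aligned
  distances, common in synthetic fixtures) lose whole boundary shells to
  rounding noise and their estimates become configuration-sensitive.
* **Degenerate input.**  Atom pairs closer than 0.01 Å are rejected with
  an error naming both records (corrupt files), and intra-residue pairs
  are never emitted as contacts.
* **Deterministic aggregation.**  Residue sums accumulate over a
  serial-sorted contact list, so totals are bit-identical under input
  permutation; the `-t` thread flag is accepted for interface
  compatibility, and the engine guarantees thread count can never change
  an output byte (it is single-threaded).

### Convergence study and pinned tolerances

On 50 random two-sphere configurations (radii 1.5–3.5 Å, overlap
0.2–2.0 Å) the grid area stays within 3% of the analytic spherical-cap
value at 5000 points and within 1.5% at 15092.  Volume behaves
differently: the absolute error stays below 0.35 Å³ at 0.2 Å spacing
(0.06 Å³ at 0.1 Å), but a *relative* bound cannot hold uniformly —
a lens thinner than the lattice spacing (overlaps near 0.2 Å produce
lenses under 0.3 Å³) is at the resolution limit of any fixed grid.  The
pinned test tolerances are therefore mixed: `max(3% relative, 0.35 Å³)`
at default and `max(3%, 0.06 Å³)` at enhanced precision.  Refinement is
asserted suite-wide — enhanced precision strictly reduces both the
maximum and the mean error of each series, and per-configuration
wherever the coarse error exceeds the fine discretization scale.  A
per-configuration *strict* reduction everywhere is not attainable for an
unbiased estimator: when the coarse error is accidentally near zero,
refinement cannot beat it.

## What the synthetic fixtures do and do not show

All tests run on programmatically generated inputs: isolated sphere
pairs, short ideal-geometry peptides, random atom clouds, and
multi-model ensembles with prescribed rigid displacements.  These
exercise every code path — parsing, radii, sharing, classification,
aggregation, ensembles, hydration profiling — against closed-form or
brute-force oracles.  They do not emulate real experimental structures:
no alternate-conformer disorder beyond simple altLoc cases, no missing
atoms mid-chain, no crystal packing, and ensemble displacements are
rigid rather than conformational.  Passing tests therefore demonstrate
the correctness of the geometry and bookkeeping, not agreement with any
particular experimental dataset; on real NMR ensembles the suggested
0.5 Å²/0.25 Å³ cutoffs matter because the spherical approximation
produces many thin artifact contacts.

Problem sizes used throughout (50 oracle configurations, 15-atom
peptides, 40-model two-residue ensembles, 10⁶-point Monte-Carlo checks
of the closed forms) were chosen so the full suite exercises every
invariant at high resolution while remaining a desk-scale computation.

## Known limitations

* Heavy atoms only; hydrogens are dropped at parse time, so hydrogen
  bonds are typed by donor/acceptor distance, not geometry.
* The donor/acceptor/aromatic table covers the 20 standard amino acids;
  non-standard residues fall back to element classes and their
  bond-ambiguous contacts are reported under UNDEF columns rather than
  guessed.
* First alternate location wins; occupancies are ignored.
* mmCIF is out of scope; inputs are PDB-format files.
* The volume grid cannot resolve lenses thinner than its spacing; use
  enhanced precision when sub-0.3 Å³ contacts matter.
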