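---
title: "Methods: glycan fragment mapping of a glycosidase binding canyon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glycan fragment mapping of a glycosidase binding canyon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators and numerical choices
behind `glycanyon`, in the spirit of a methods section: what each stage
assumes, which tunables matter, and what a green test does and does not
establish.

## Ring puckering

Six-membered sugar rings are summarised by Cremer–Pople coordinates
computed over the canonical atom order O5, C1, …, C5 (ring oxygen first).
The mean plane passes through the geometric centre with its orientation
fixed by the sine/cosine weighted position sums; perpendicular
displacements decompose into a pseudorotational pair (q₂, φ₂) and the
chair amplitude q₃, giving total amplitude Q = √(q₂²+q₃²), polar angle
θ = atan2(q₂, q₃) and phase φ = φ₂.

Conventions differ across the literature; here the pole assignment
**θ = 0 ↔ ⁴C₁** for a D-pyranose in this atom order is asserted by a
fixture built from an ideal ⁴C₁ D-mannose and locked by test. The inverse
transform places atoms clockwise on a circle (default radius 1.45 Å) so
that the forward construction's right-hand-rule normal points along +z;
forward∘inverse is the identity to 10⁻⁶ over a (Q, θ, φ) grid.

Classification snaps (θ, φ) to the nearest of 38 canonical conformers by
great-circle distance: 2 chairs at the poles, 6 boats and 6 skew-boats
alternating every 30° on the equator, and 12 envelopes + 12 half-chairs
alternating every 30° on the two tropics. The tropics are placed at the
tetrahedral latitude (54.74° / 125.26°) as a simplified grid — canonical
half-chairs sit at 50.8°/129.2°, but on a 30° φ grid the ≤ 5° latitude
difference never changes the nearest reference point. States farther than
`like_threshold` (default 15°, configurable) from every reference gain a
`-like` suffix, mirroring the hedged naming used for distorted rings.
Rings with Q < 0.05 Å are reported as `planar` and never classified.

## Glycan topology

Covalent bonds are inferred from a single heavy-atom distance cutoff of
1.8 Å; CONECT records are ignored because deposited HETATM connectivity is
unreliable. A pyranose ring is a 6-cycle of five carbons and one oxygen
inside one residue; the anomeric carbon is the ring carbon adjacent to the
ring oxygen bearing an exocyclic oxygen (falling back to the atom named C1
when that oxygen is engaged in a glycosidic bond). Acceptor positions are
read from the PDB carbohydrate atom names (C2/C3/C4/C6), not re-derived
from geometry.

Anomericity is assigned without hydrogens: the signed perpendicular
displacements (relative to the donor ring's mean plane) of the anomeric
exocyclic oxygen and of the C6 reference substituent at C5 are compared —
opposite signs α, same signs β (D-sugar convention). Two guards apply:

- a displacement of the anomeric oxygen below 0.15 Å, or a planar donor
  ring, yields `undetermined` rather than a guess;
- when the **C6 reference** displacement falls inside the dead zone — as
  happens at B₂,₅, where C5 is a prow atom and its substituent is
  isoclinal (measured displacement ≈ −0.11 Å) — the C6 side is recovered
  from the local chirality at C5: which of the two ideal tetrahedral
  exocyclic directions C6 occupies is conformation-invariant, so the side
  it would take in the chair is used. Without this fallback the
  displacement rule cannot type anomers on transition-state-like rings.

L-sugars, ketoses and furanoses are out of scope; all built-in chemistry
is D-aldopyranose (Man, Glc, GlcN).

## Superposition

Kabsch fitting uses the SVD of the weighted covariance with a determinant
correction to exclude reflections; collinear point sets are rejected.
Sequence-guided alignment seeds Cα pairs from a global BLOSUM62 alignment
(gap open 10, extend 0.5 — values fixed in configuration since published
r.m.s.d. figures rarely state them), then iterates fit → reject →
refit. Rejection is *progressively trimmed*: each cycle removes only
pairs deviating beyond max(`reject_cutoff`, 0.8 × the worst deviation), so
a fit tilted by gross outliers does not drag well-fitting neighbours over
the cutoff; retained-pair r.m.s.d. is non-increasing across cycles and no
pair is re-admitted. Defaults `max_cycles = 5`, `reject_cutoff = 2.0 Å`
emulate interactive-graphics "align" behaviour.

## Subsite mapping

Sugars from every complex are mapped into the reference frame by the
sequence-guided transform (complexes retaining < 50 Cα pairs are skipped
with a warning). Ring centroids are clustered by single linkage at
`merge_radius` (default 1.8 Å — below inter-subsite spacing of linked
pyranoses, ~4–6 Å, and above coordinate noise).

Labelling anchors +1 on the cluster containing a supplied glucosamine
ring, else on the cluster nearest the DD-motif carboxylate midpoint. The
remaining subsites are ordered by nearest-neighbour chaining from +1,
growing two arms. Published subsite maps give only labels, not an
algorithm, so the sign rule is a design choice: when a wing-region (WR1)
annotation exists, the arm whose far end lies nearest WR1 is negative
(WR1 extends the canyon at −5/−6); without one, the shorter arm is
positive (+3…−6 geometry); a single-arm chain is negative, so a terminal
anchor yields +1, −1, −2, −3.

Occupancy matrices carry one row per (glycan species, source structure) —
several monosaccharide entities of the same species in one soak share a
row — and one column per subsite. Reassembly picks one representative
sugar per path subsite (highest mean occupancy, ties by source id then
residue order, for determinism), checks linkage-plausible adjacency
(≤ 4.5 Å) with a warning, and reports the shape descriptor: end-to-end
distance from C1 of the path's first ring to C4 of its last, normalised
per residue. Shape classes use per-residue thresholds ≥ 4.0 Å linear and
≤ 2.5 Å U (C between), calibrated once against three published exemplars
(19.4 Å/5 residues linear, 11.3 Å/4 residues C, 7.8 Å U) and stored in
configuration; they are deliberately not tuned further because the
residue count of the published U-shaped case is not printed.

## Family analysis

Pairwise statistics share the structural alignment configuration. Identity
is identical columns over aligned (non-double-gap) columns of the global
alignment; significance comes from a separate local alignment converted
with fixed gapped Karlin–Altschul parameters (λ = 0.267, K = 0.041,
search space m·n) — a deterministic approximation of BLAST-style
statistics, not a re-fit. Representative nodes collapse sequences
greedily (length-sorted, first representative at ≥ 90 % identity),
mirroring CD-HIT-like practice; the SSN keeps edges at
`evalue_cutoff` (default 10⁻⁴⁰) between representatives and derives
subfamily candidates as connected components. Edges and components are
monotone in the cutoff by construction.

Conservation is a Jensen–Shannon divergence between each column's
gap-excluded frequency vector and the BLOSUM62 background, normalised by
the largest point-mass divergence over the column's observed letters.
JSD is convex in its first argument, so the score is bounded by 1 with
equality exactly for invariant columns: any fully conserved column scores
1.0 and a background-distributed column scores 0. This is an intentional
simplification standing in for Bayesian evolutionary-rate estimation;
columns with > 50 % gaps are flagged low-confidence rather than scored
trustworthy.

## The synthetic world

The generators state the conditions under which the pipeline is tested;
their defaults are fixed, not tuned:

- **Sugars** are ideal D-pyranoses: ring from the inverse Cremer–Pople
  transform (radius 1.45 Å), substituents at ideal bond lengths (C–C
  1.52 Å, C–O 1.43 Å, anomeric C–O 1.41 Å) in tetrahedral directions.
  Stereochemistry is encoded as chirality signs measured once on the ⁴C₁
  reference and reused at any pucker, so a distorted sugar keeps its
  configuration.
- **Glycans** realise each linkage by exact internal-coordinate placement
  (three-point rigid fit) at specified (φ, ψ) torsions, with a 2.0 Å
  inter-residue clash floor and bounded torsion nudging. A small
  Nelder–Mead search (`tune_glycan_torsions`) reproduces published
  end-to-end distances.
- **Complexes** plant sugars on a rigid poly-residue arc ("toy canyon")
  with parameterizable subsite centroids 6.0 Å apart — the roomy end of
  linked-pyranose spacing, chosen so independently oriented fragment
  observations cannot approach within the 1.8 Å bond-inference cutoff and
  fuse chemically; co-planted fragments are additionally kept ≥ 1.9 Å
  apart. Monosaccharides lie with their bulkiest substituent pointing out
  of the canyon and a random azimuthal spin; oligosaccharides are oriented
  along the canyon. Positional jitter is an isotropic Gaussian whose σ is
  the **RMS of the 3-D displacement** (per component σ/√3): under a
  per-component reading, 0.6 Å jitter would split three-observation
  subsites under single linkage at 1.8 Å about 18 % of the time, which
  would contradict the stated 100 %-recovery world; under the RMS reading
  the split probability is ~4×10⁻⁴.
- **Families** derive paralogs from independent random founders by seeded
  point mutation; within-family identity to the founder is hit exactly by
  construction (mutated-position count), while between-family identity is
  whatever unrelated random sequences give (near background) and is
  validated as an upper bound only.
- **MSAs** draw noise columns from the background and fix designed
  columns to single (rarer-half) residues.

What the toy world does **not** emulate: electron density and partial
occupancy (mutually exclusive overlapping fragments can coexist in one
synthetic soak), solvent, crystallographic symmetry, realistic backbone
geometry of the scaffold, correlated orientations of linked sugars across
subsites, and database-scale sequence redundancy. A green synthetic test
therefore establishes algorithmic correctness — recovery of planted
ground truth — not agreement with any particular deposited structure;
the latter requires the real PDB entries and is kept as a separate,
network-dependent workflow.

## Numerical conventions

- Planarity threshold Q < 0.05 Å; anomeric dead zone 0.15 Å; covalent
  cutoff 1.8 Å; disulfide SG–SG cutoff 2.5 Å; hydrogen-bond contact table
  3.6 Å; canyon lining 4.5 Å.
- φ is reported in [0, 360) with the poles' φ fixed at 0; values within
  10⁻⁹ of 360 wrap to 0.
- Ties everywhere break deterministically: altloc by occupancy then
  character order, representative sugars by source id then residue order,
  node collapse by length then input order.
- Pipeline outputs are written with fixed precision (3 decimals for
  Ångström quantities, 4 for scores) and contain no timestamps, so reruns
  under one seed are byte-identical.

## Known limitations

- Anomericity on exotic puckers far from the tested itinerary
  (⁴C₁, ᴼS₂, B₂,₅ and the planarized control) relies on the chirality
  fallback being consistent with the mean-plane rule; both agree on the
  tested states.
- The Karlin–Altschul parameters are fixed constants; E-values are
  comparable within this package but not calibrated against any BLAST
  release.
- `compare_occupancy` assigns predicted sugars by centroid distance
  (default 2.5 Å) to observed subsites; it does not validate predicted
  geometry beyond position.
- The nearest-neighbour label chaining assumes an essentially 1-D canyon;
  genuinely branched sites would need manual labels.
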